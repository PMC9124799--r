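task: patterns
tau_m: 15
tau_out: 10
tau_a: 200
tau_ls: 10
v_th: 1
beta_adapt: 0.4902
t_refrac: 5
d: 1
dt: 1
g_l: 1
g_b: 1
C_m: 15
tau_L: 10
tau_s: 2
f_target: 20
f_target_psnn: 20
lam_f: 1
lam_v: 0.01
eta1: 0.1
eta2: 10
sigma1: 1
sigma2: 4
lam_mix: 0.5
lam_trainable: TRUE
lr: 0.001915
lr_out: 0.002
lr_lam: 0.0002
n_batch: 285
n_iters: 100
eta_inner: 0.01
grad_clip: 100
n_tlif: 180
n_lif: 260
n_psnn: 239
q_ada: 0.405
t_img: 20
n_classes: 1000
n_per_class: 25
n_neurons: 100
duration_ms: 200
rate_min: 2
rate_max: 50
sigma_noise: 0
p_del: 0
flip_frac: 0.15
n_way: 5
k_shot: 1
motor_duration_ms: 500
n_clock: 20
L1: 0.5
L2: 0.5
init_gain: 1
seed: 1
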