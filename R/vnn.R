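#' Convolutional encoder (visual pathway) initialization
#'
#' A three-layer 2-D ConvNet of non-spiking (ReLU) units used to encode
#' 28 x 28 grayscale images into the input channels of the spiking
#' learner: per block a 3 x 3 same-padding convolution (16, 32, 64
#' filters), inference-mode batch normalization, ReLU, and 2 x 2 average
#' pooling, giving 64 x 3 x 3 = 576 features.
#'
#' @param n_filters Filters per layer.
#' @param seed Integer seed for the weight draw (He-scaled normal).
#' @return An object of class `vnn_weights`.
#' @export
vnn_init <- function(n_filters = c(16, 32, 64), seed = 1L) {
  set.seed(as.integer(seed))
  n_in <- c(1, n_filters[-length(n_filters)])
  layers <- lapply(seq_along(n_filters), function(l) {
    fan_in <- 9 * n_in[l]
    list(W = array(stats::rnorm(9 * n_in[l] * n_filters[l],
                                sd = sqrt(2 / fan_in)),
                   c(3, 3, n_in[l], n_filters[l])),
         b = numeric(n_filters[l]),
         bn_mean = numeric(n_filters[l]), bn_var = rep(1, n_filters[l]),
         bn_gamma = rep(1, n_filters[l]), bn_beta = numeric(n_filters[l]))
  })
  structure(list(layers = layers, n_filters = n_filters),
            class = "vnn_weights")
}

# 3x3 same-padding convolution of an H x W x C array with a
# 3 x 3 x C x K kernel, via shifted accumulation.
.conv3x3 <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]; K <- dim(W)[4]
  xp <- array(0, c(H + 2, Wd + 2, C))
  xp[2:(H + 1), 2:(Wd + 1), ] <- x
  out <- array(rep(b, each = H * Wd), c(H, Wd, K))
  for (dy in 0:2) for (dx in 0:2) {
    patch <- matrix(xp[dy + seq_len(H), dx + seq_len(Wd), ], H * Wd, C)
    out <- out + array(patch %*% matrix(W[dy + 1, dx + 1, , ], C, K),
                       c(H, Wd, K))
  }
  out
}

.avg_pool2 <- function(x) {
  H <- dim(x)[1] %/% 2; W <- dim(x)[2] %/% 2; C <- dim(x)[3]
  x <- x[seq_len(2 * H), seq_len(2 * W), , drop = FALSE]
  0.25 * (x[seq(1, 2 * H, 2), seq(1, 2 * W, 2), , drop = FALSE] +
            x[seq(2, 2 * H, 2), seq(1, 2 * W, 2), , drop = FALSE] +
            x[seq(1, 2 * H, 2), seq(2, 2 * W, 2), , drop = FALSE] +
            x[seq(2, 2 * H, 2), seq(2, 2 * W, 2), , drop = FALSE])
}

#' Encode a grayscale image into feature channels
#'
#' Deterministic forward pass of the convolutional encoder (inference-mode
#' batch normalization), producing the flattened feature vector that
#' drives the spiking learner's input channels as analog currents.
#'
#' @param image `28 x 28` numeric matrix in `[0, 1]`.
#' @param vnn A [vnn_init()] object.
#' @return Numeric feature vector (length 576 for the default
#'   architecture).
#' @export
conv_encode <- function(image, vnn) {
  if (!is.matrix(image) || nrow(image) != 28 || ncol(image) != 28)
    stop("expected a 28 x 28 grayscale image matrix")
  x <- array(image, c(28, 28, 1))
  for (ly in vnn$layers) {
    x <- .conv3x3(x, ly$W, ly$b)
    # inference batchnorm per channel
    sc <- ly$bn_gamma / sqrt(ly$bn_var + 1e-5)
    x <- sweep(sweep(x, 3, ly$bn_mean, `-`), 3, sc, `*`)
    x <- sweep(x, 3, ly$bn_beta, `+`)
    x <- pmax(x, 0)
    x <- .avg_pool2(x)
  }
  as.numeric(x)
}

#' Load an Omniglot-layout image directory
#'
#' Reads a directory laid out as `alphabet/character/sample.png` into a
#' list of 28 x 28 grayscale matrices grouped by character class. Requires
#' the `png` package; entirely optional — no built-in task depends on
#' image data.
#'
#' @param path Directory root.
#' @param max_classes Optional cap on the number of classes loaded.
#' @return List of classes, each a list of image matrices.
#' @export
read_image_classes <- function(path, max_classes = Inf) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required to load image directories")
  alphabets <- list.dirs(path, recursive = FALSE)
  classes <- unlist(lapply(alphabets, list.dirs, recursive = FALSE))
  classes <- utils::head(classes, max_classes)
  lapply(classes, function(cl) {
    lapply(list.files(cl, pattern = "\\.png$", full.names = TRUE),
           function(f) {
             img <- png::readPNG(f)
             if (length(dim(img)) == 3) img <- img[, , 1]
             if (!all(dim(img) == c(28, 28))) {
               # nearest-neighbour resize to 28 x 28
               ri <- round(seq(1, nrow(img), length.out = 28))
               ci <- round(seq(1, ncol(img), length.out = 28))
               img <- img[ri, ci]
             }
             img
           })
  })
}
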