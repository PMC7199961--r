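#' Declarative CNN architecture for 110 x 4 chimera input
#'
#' Builds the default network: four length-preserving Conv1D blocks
#' (16, 32, 64, 128 filters with kernel sizes 2, 3, 4, 5, each followed by
#' max-pooling of size 2 with ceiling length semantics), then flatten,
#' dropout, a 128-unit ReLU dense layer with L2 weight decay, dropout, and
#' a single sigmoid output unit giving the probability that the chimera is
#' a genuine miRNA:target-site interaction.
#'
#' @param dropout_rates length-2 numeric: rates for the dropout layer after
#'   flatten and after the 128-unit dense layer. Default `c(0.5, 0.3)`.
#' @param l2 L2 penalty coefficient on the 128-unit dense layer's weights.
#'   Default `1e-3`.
#' @return a list of class `cnn_arch` with `input_length`, `input_channels`
#'   and `layers` (ordered list of layer specs).
#' @export
build_architecture <- function(dropout_rates = c(0.5, 0.3), l2 = 1e-3) {
  stopifnot(length(dropout_rates) == 2L, all(dropout_rates >= 0),
            all(dropout_rates < 1), l2 >= 0)
  conv <- function(f, k) list(kind = "conv", filters = as.integer(f),
                              kernel_size = as.integer(k),
                              activation = "relu")
  pool <- function() list(kind = "maxpool", pool_size = 2L)
  layers <- list(
    conv(16, 2), pool(), conv(32, 3), pool(), conv(64, 4), pool(),
    conv(128, 5), pool(),
    list(kind = "flatten"),
    list(kind = "dropout", dropout_rate = dropout_rates[1]),
    list(kind = "dense", units = 128L, activation = "relu",
         l2_coefficient = l2),
    list(kind = "dropout", dropout_rate = dropout_rates[2]),
    list(kind = "dense", units = 1L, activation = "sigmoid",
         l2_coefficient = 0)
  )
  structure(list(input_length = CHIMERA_LENGTH, input_channels = 4L,
                 layers = layers),
            class = "cnn_arch")
}

#' Per-layer output shapes of an architecture
#'
#' Convolutions are length-preserving ("same" padding); max-pooling maps a
#' length L to `ceiling(L / pool_size)`; flatten turns (L, C) into L*C
#' units; dense layers set the unit count.
#'
#' @param arch a [build_architecture()] spec.
#' @param input_length input length (default the spec's 110).
#' @return a `data.frame` with columns `layer` (kind), `length` and
#'   `channels`; after flatten, `length` holds the unit count and
#'   `channels` is `NA`.
#' @export
output_shapes <- function(arch, input_length = arch$input_length) {
  stopifnot(inherits(arch, "cnn_arch"))
  len <- as.integer(input_length)
  ch <- arch$input_channels
  flat <- FALSE
  rows <- lapply(arch$layers, function(ly) {
    switch(ly$kind,
      conv = { ch <<- ly$filters },
      maxpool = { len <<- as.integer(ceiling(len / ly$pool_size)) },
      flatten = { len <<- len * ch; ch <<- NA_integer_; flat <<- TRUE },
      dropout = NULL,
      dense = { len <<- ly$units; ch <<- NA_integer_ },
      stop("unknown layer kind: ", ly$kind)
    )
    data.frame(layer = ly$kind, length = len, channels = ch,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-layer and total trainable parameter counts
#'
#' A Conv1D layer has `filters * (kernel_size * in_channels + 1)` weights
#' (bias included); a dense layer `units * (in_dim + 1)`; pooling, flatten
#' and dropout contribute nothing.
#'
#' @param arch a [build_architecture()] spec.
#' @return a list with `per_layer` (`data.frame` of `layer`, `params`) and
#'   `total`.
#' @export
count_parameters <- function(arch) {
  stopifnot(inherits(arch, "cnn_arch"))
  len <- arch$input_length
  ch <- arch$input_channels
  rows <- lapply(arch$layers, function(ly) {
    p <- switch(ly$kind,
      conv = {
        p <- ly$filters * (ly$kernel_size * ch + 1L)
        ch <<- ly$filters
        p
      },
      maxpool = { len <<- as.integer(ceiling(len / ly$pool_size)); 0L },
      flatten = { ch <<- len * ch; 0L },  # ch now holds the flat width
      dropout = 0L,
      dense = { p <- ly$units * (ch + 1L); ch <<- ly$units; p }
    )
    data.frame(layer = ly$kind, params = as.integer(p),
               stringsAsFactors = FALSE)
  })
  per_layer <- do.call(rbind, rows)
  list(per_layer = per_layer, total = sum(per_layer$params))
}

#' @export
print.cnn_arch <- function(x, ...) {
  shapes <- output_shapes(x)
  counts <- count_parameters(x)
  cat(sprintf("CNN architecture: input %d x %d\n", x$input_length,
              x$input_channels))
  df <- cbind(shapes, params = counts$per_layer$params)
  print(df, row.names = FALSE)
  cat(sprintf("Total params: %s\n", format(counts$total, big.mark = ",")))
  invisible(x)
}
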