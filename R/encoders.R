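#' Sequence window encodings
#'
#' Three encodings turn a C-centred window of length `L = 2*delta+1` into a
#' numeric vector:
#'
#' * **one-hot** (`4L` values): each base contributes A=\[1,0,0,0\],
#'   C=\[0,1,0,0\], G=\[0,0,1,0\], T=\[0,0,0,1\]; `N` contributes zeros.
#' * **DPF** (`4L` values): per position the three deoxynucleotide chemical
#'   properties -- ring structure (1 for purines A/G), functional group
#'   (1 for amino bases A/C), hydrogen bond (1 for weakly paired A/T) --
#'   followed by the cumulative frequency of the position's base among
#'   positions 1..k, divided by k. `N` gets properties (0,0,0); its
#'   cumulative frequency counts literal `N` matches.
#' * **fused** (`8L` values): one-hot followed by DPF.
#'
#' @param window A single window string (`encode_one_hot`, `encode_dpf`,
#'   `encode_fused`) over `A,C,G,T,N`.
#' @return A numeric vector with all entries in `[0, 1]`.
#' @examples
#' encode_one_hot("ACGT")
#' encode_dpf("ACGT")       # lambda = 1, 1/2, 1/3, 1/4
#' @name encoders
NULL

.onehot_map <- matrix(c(1, 0, 0, 0,
                        0, 1, 0, 0,
                        0, 0, 1, 0,
                        0, 0, 0, 1,
                        0, 0, 0, 0),
                      nrow = 5, byrow = TRUE,
                      dimnames = list(c("A", "C", "G", "T", "N"), NULL))

# ring structure, functional group, hydrogen bond
.property_map <- matrix(c(1, 1, 1,
                          0, 1, 0,
                          1, 0, 0,
                          0, 0, 1,
                          0, 0, 0),
                        nrow = 5, byrow = TRUE,
                        dimnames = list(c("A", "C", "G", "T", "N"), NULL))

window_chars <- function(window) {
  window <- toupper(window)
  check_alphabet(window)
  strsplit(window, "")[[1]]
}

#' @rdname encoders
#' @export
encode_one_hot <- function(window) {
  chars <- window_chars(window)
  as.vector(t(.onehot_map[chars, , drop = FALSE]))
}

#' @rdname encoders
#' @export
encode_dpf <- function(window) {
  chars <- window_chars(window)
  k <- seq_along(chars)
  # cumulative count of the base at position k among positions 1..k
  counts <- vapply(k, function(i) sum(chars[seq_len(i)] == chars[i]),
                   numeric(1))
  lambda <- counts / k
  props <- .property_map[chars, , drop = FALSE]
  as.vector(t(cbind(props, lambda)))
}

#' @rdname encoders
#' @export
encode_fused <- function(window) {
  c(encode_one_hot(window), encode_dpf(window))
}

encoding_width <- function(encoding, delta) {
  L <- 2L * delta + 1L
  switch(encoding, onehot = 4L * L, dpf = 4L * L, fused = 8L * L,
         stop("unknown encoding '", encoding, "'"))
}

#' Encode a batch of windows into a feature matrix
#'
#' @param samples Sample data frame (or character vector of windows); all
#'   windows must share one length.
#' @param encoding `"onehot"`, `"dpf"` or `"fused"`.
#' @return Numeric matrix, one row per window, with attributes `encoding`
#'   and `delta`.
#' @export
encode_batch <- function(samples, encoding = c("onehot", "dpf", "fused")) {
  encoding <- match.arg(encoding)
  windows <- if (is.data.frame(samples)) samples$window else samples
  if (length(windows) == 0L) {
    # width unknown without a delta; use 0 columns only if none supplied
    delta <- if (is.data.frame(samples)) attr(samples, "delta") else NULL
    d <- if (is.null(delta)) 0L else encoding_width(encoding, delta)
    m <- matrix(numeric(0), nrow = 0L, ncol = d)
    attr(m, "encoding") <- encoding
    return(m)
  }
  L <- unique(nchar(windows))
  if (length(L) != 1L) {
    stop("windows of mixed length in one batch: ", paste(L, collapse = ", "))
  }
  delta <- (L - 1L) %/% 2L
  enc_fun <- switch(encoding, onehot = encode_one_hot, dpf = encode_dpf,
                    fused = encode_fused)
  d <- encoding_width(encoding, delta)
  m <- matrix(vapply(windows, enc_fun, numeric(d), USE.NAMES = FALSE),
              ncol = d, byrow = TRUE)
  attr(m, "encoding") <- encoding
  attr(m, "delta") <- delta
  m
}
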