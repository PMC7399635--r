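# Consensus bases planted around the central C in positive windows.
# CpG-flavoured: alternating C/G so the centre sits in a locally CpG-dense
# context, with a G immediately downstream of the central C (a CpG pair).
.motif_consensus <- function(offsets) {
  ifelse(offsets %% 2 == 0, "C", "G")
}

#' Generate a labeled synthetic benchmark of C-centred windows
#'
#' Emulates the shape of a promoter 5mC benchmark: windows of length
#' `2*delta+1` with a central C, a heavily imbalanced class ratio
#' (defaults near 1:11), and a tunable sequence signal separating the
#' classes. Negatives are i.i.d. draws from a background with the given GC
#' fraction. Positives additionally carry a planted motif of width
#' `motif_width` centred on the C: at each motif position the base is the
#' CpG-flavoured consensus with probability `effect`, otherwise a
#' background draw. At `effect = 0` the classes are exchangeable (null
#' model); at `effect` near 1 the classes are strongly separable.
#'
#' @param n_pos,n_neg Number of positive / negative windows.
#' @param delta Half-window size (window length `2*delta+1`).
#' @param effect Class-separation strength in `[0, 1]`.
#' @param gc_background Background GC fraction.
#' @param motif_width Number of motif positions flanking the central C.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return Labeled sample data frame (`window`, `label`, ...), positives
#'   first.
#' @examples
#' d <- generate_dataset(n_pos = 10, n_neg = 110, delta = 5, effect = 0.9,
#'                       seed = 1)
#' table(d$label)
#' @export
generate_dataset <- function(n_pos, n_neg, delta = 20L, effect = 0.5,
                             gc_background = 0.5, motif_width = 8L,
                             seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, delta >= 1L,
            effect >= 0, effect <= 1,
            gc_background > 0, gc_background < 1,
            motif_width >= 1L)
  L <- 2L * delta + 1L
  centre <- delta + 1L
  half <- motif_width %/% 2L
  offsets <- setdiff(seq.int(-half, half), 0L)
  offsets <- offsets[centre + offsets >= 1L & centre + offsets <= L]
  bases <- c("A", "C", "G", "T")
  bg <- c((1 - gc_background) / 2, gc_background / 2,
          gc_background / 2, (1 - gc_background) / 2)
  consensus <- .motif_consensus(offsets)

  with_seed(derive_seed(seed, 31L), {
    draw_background <- function(n) {
      m <- matrix(sample(bases, n * L, replace = TRUE, prob = bg), nrow = n)
      m[, centre] <- "C"
      m
    }
    neg <- draw_background(n_neg)
    pos <- draw_background(n_pos)
    for (j in seq_along(offsets)) {
      col <- centre + offsets[j]
      planted <- runif(n_pos) < effect
      pos[planted, col] <- consensus[j]
    }
    to_str <- function(m) do.call(paste0, as.data.frame(m))
    new_samples(c(to_str(pos), to_str(neg)),
                label = rep(c(1L, 0L), c(n_pos, n_neg)),
                source_id = "synthetic",
                center_pos = NA_integer_,
                source_strand = "+")
  })
}

#' Generate a random toy promoter sequence
#'
#' A uniform ACGT sequence for exercising candidate scanning and the
#' end-to-end prediction pipeline.
#'
#' @param length Sequence length in nucleotides.
#' @param seed Integer seed.
#' @param id Record id.
#' @param strand `"+"` or `"-"`.
#' @return One-row data frame with columns `id`, `seq`, `strand`.
#' @export
make_toy_promoter <- function(length, seed = 1L, id = "toy_promoter",
                              strand = "+") {
  stopifnot(length >= 1L)
  seq <- with_seed(derive_seed(seed, 37L),
                   paste(sample(c("A", "C", "G", "T"), length,
                                replace = TRUE), collapse = ""))
  data.frame(id = id, seq = seq, strand = strand, stringsAsFactors = FALSE)
}
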