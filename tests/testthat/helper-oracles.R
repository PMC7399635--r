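# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own vectorised code paths.

oracle_one_hot <- function(window) {
  map <- list(A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0),
              T = c(0, 0, 0, 1), N = c(0, 0, 0, 0))
  unlist(lapply(strsplit(window, "")[[1]], function(ch) map[[ch]]),
         use.names = FALSE)
}

oracle_dpf <- function(window) {
  props <- list(A = c(1, 1, 1), C = c(0, 1, 0), G = c(1, 0, 0),
                T = c(0, 0, 1), N = c(0, 0, 0))
  chars <- strsplit(window, "")[[1]]
  out <- numeric(0)
  for (k in seq_along(chars)) {
    count <- 0
    for (j in 1:k) if (chars[j] == chars[k]) count <- count + 1
    out <- c(out, props[[chars[k]]], count / k)
  }
  out
}

# Exhaustive pair-counting AUC (Mann-Whitney with ties = 1/2).
oracle_auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

random_window <- function(L, alphabet = c("A", "C", "G", "T")) {
  chars <- sample(alphabet, L, replace = TRUE)
  chars[(L + 1) %/% 2] <- "C"
  paste(chars, collapse = "")
}

# Small, fast network configuration for tests that only need the plumbing,
# not predictive power.
tiny_config <- function(seed = 1L) {
  submodel_config(hidden_layers = c(16L), epochs = 15L, batch_size = 32L,
                  seed = seed)
}
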