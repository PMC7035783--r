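# Independent brute-force oracles, written without reusing the package's
# internals.

# All ATG..stop candidate ORFs by naive scanning; returns the maximal
# nucleotide length and its amino-acid length under the same conventions
# (stop included in nt length, excluded from aa length; no in-frame stop
# means run to the last complete codon; codons with N are inert).
oracle_max_orf <- function(seq) {
  n <- nchar(seq)
  best_nt <- 0L
  best_aa <- 0L
  for (frame in 0:2) {
    m <- (n - frame) %/% 3
    if (m < 1) next
    codons <- character(m)
    for (i in seq_len(m)) {
      codons[i] <- substr(seq, frame + 3 * (i - 1) + 1, frame + 3 * i)
    }
    for (i in seq_len(m)) {
      if (codons[i] != "ATG") next
      j <- i
      stopped <- FALSE
      while (j <= m) {
        if (codons[j] %in% c("TAA", "TAG", "TGA")) {
          stopped <- TRUE
          break
        }
        j <- j + 1
      }
      if (stopped) {
        nt <- 3 * (j - i + 1)
        aa <- j - i
      } else {
        nt <- 3 * (m - i + 1)
        aa <- m - i + 1
      }
      if (nt > best_nt) {
        best_nt <- nt
        best_aa <- aa
      }
    }
  }
  list(nt_length = best_nt, aa_length = best_aa)
}

# Reference re-implementation of the Fickett TESTCODE lookup, written as
# explicit per-base branching over the published tables.
oracle_fickett <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(chars) == 0) return(0)
  pos_tab <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
  )
  con_tab <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
  )
  pos_w <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  con_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  pos_cuts <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  con_cuts <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
  # NOTE: position index follows the original full-sequence phase (Ns keep
  # their place), matching the statistic's definition on the raw sequence
  chars_all <- strsplit(seq, "")[[1]]
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- numeric(3)
    for (i in seq_along(chars_all)) {
      if (chars_all[i] == b) {
        cnt[(i - 1) %% 3 + 1] <- cnt[(i - 1) %% 3 + 1] + 1
      }
    }
    posv <- max(cnt) / (min(cnt) + 1)
    conv <- sum(cnt) / length(chars)
    pi <- NA
    for (k in seq_along(pos_cuts)) {
      if (posv >= pos_cuts[k]) { pi <- k; break }
    }
    ci <- NA
    for (k in seq_along(con_cuts)) {
      if (conv >= con_cuts[k]) { ci <- k; break }
    }
    total <- total + pos_tab[[b]][pi] * pos_w[[b]] + con_tab[[b]][ci] * con_w[[b]]
  }
  total
}

# Hypergeometric upper tail P(X >= k) by direct summation of the density.
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
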