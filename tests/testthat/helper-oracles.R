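# Independent brute-force oracles, written directly from the defining
# formulas with explicit loops. They deliberately share no code with the
# package implementations they check.

oracle_igr <- function(bins, labels) {
  n <- length(bins)
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  h_c <- ent(table(labels))
  h_f <- ent(table(bins))
  if (h_f == 0) return(0)
  h_cf <- 0
  for (v in unique(bins)) {
    idx <- bins == v
    h_cf <- h_cf + (sum(idx) / n) * ent(table(labels[idx]))
  }
  (h_c - h_cf) / h_f
}

oracle_pssm <- function(scores, lambda_max) {
  L <- nrow(scores)
  E <- matrix(NA_real_, L, 20)
  for (i in seq_len(L)) for (j in 1:20) E[i, j] <- 1 / (1 + exp(-scores[i, j]))
  out <- numeric(0)
  for (lam in seq_len(lambda_max)) {
    for (i in 1:20) {
      acc <- 0
      for (j in seq_len(L - lam)) acc <- acc + (E[j, i] - E[j + lam, i])^2
      out <- c(out, acc / (L - lam))
    }
  }
  out
}

oracle_distribution <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- numeric(20)
  for (a in seq_along(aas)) {
    pos <- which(chars == aas[a])
    if (length(pos) < 2) next
    d <- pos - pos[1]
    out[a] <- sum((d - mean(d))^2) / length(d)
  }
  out
}

oracle_transition <- function(sequence) {
  scheme <- functional_group_scheme()
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  grp <- function(ch) names(scheme)[vapply(scheme, function(m) ch %in% m, logical(1))]
  groups <- vapply(chars, grp, character(1))
  out <- numeric(0)
  gn <- names(scheme)
  for (i in 1:9) for (j in (i + 1):10) {
    cnt <- 0
    if (L >= 2) {
      for (p in seq_len(L - 1)) {
        if ((groups[p] == gn[i] && groups[p + 1] == gn[j]) ||
            (groups[p] == gn[j] && groups[p + 1] == gn[i])) cnt <- cnt + 1
      }
    }
    out <- c(out, cnt / L)
  }
  out
}

# maximal-run statistics by explicit scan
oracle_segments <- function(flag) {
  lens <- integer(0)
  cur <- 0L
  for (v in flag) {
    if (v) cur <- cur + 1L
    else if (cur > 0L) { lens <- c(lens, cur); cur <- 0L }
  }
  if (cur > 0L) lens <- c(lens, cur)
  lens
}

oracle_pseaac <- function(sequence, eta = 20, w = 0.05) {
  scales <- property_scales()
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  Theta <- function(a, b) mean((scales[a, ] - scales[b, ])^2)
  theta <- numeric(eta)
  for (k in seq_len(eta)) {
    s <- 0
    for (j in seq_len(L - k)) s <- s + Theta(chars[j], chars[j + k])
    theta[k] <- s / (L - k)
  }
  aas <- rownames(scales)
  f <- vapply(aas, function(a) sum(chars == a) / L, numeric(1))
  denom <- 1 + w * sum(theta)
  unname(c(f / denom, w * theta / denom))
}

# DWT analysis step via FFT-based full convolution (a different numerical
# route from the package's explicit dot-product loop)
oracle_dwt_step <- function(x, filt) {
  p <- length(filt) - 1
  xp <- c(rev(x[1:p]), x, rev(x)[1:p])
  full <- stats::convolve(xp, rev(filt), type = "open")
  valid <- full[(p + 1):(length(xp))]
  valid[seq(2, length(valid), by = 2)]
}

oracle_dwt <- function(x, level) {
  lo <- ecmforest:::DB4_DEC_LO
  hi <- ecmforest:::DB4_DEC_HI
  details <- list()
  a <- x
  for (l in seq_len(level)) {
    details[[l]] <- oracle_dwt_step(a, hi)
    a <- oracle_dwt_step(a, lo)
  }
  list(approximation = a, details = details)
}

random_record <- function(len, seed) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seq <- withr_seed(seed, paste(sample(aas, len, replace = TRUE), collapse = ""))
  protein_record(paste0("r", seed), seq)
}

withr_tempfile <- function(lines) {
  path <- tempfile()
  writeLines(lines, path)
  path
}

# local seed sandbox for test helpers
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
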