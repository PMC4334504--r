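make_profile <- function(scores, id = "t") {
  colnames(scores) <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  structure(list(id = id, residues = strrep("A", nrow(scores)), scores = scores),
            class = "pssm_profile")
}

test_that("pssm_features applies the sigmoid then lagged squared differences", {
  # identical rows: every lagged difference vanishes
  same <- make_profile(matrix(rep(seq(-3, 3, length.out = 20), each = 8), 8, 20))
  expect_equal(max(abs(pssm_features(same))), 0)

  # sigmoid(0) = 0.5 feeds the differencing
  alt <- make_profile(matrix(rep(c(0, 2), each = 20, times = 3), 6, 20, byrow = TRUE))
  v <- pssm_features(alt, pssm_params(lambda_max = 1))
  expect_equal(unname(v[1]), (0.5 - 1 / (1 + exp(-2)))^2, tolerance = 1e-12)

  for (s in c(5, 17)) {
    scores <- withr_seed(s, matrix(rnorm(12 * 20, sd = 3), 12, 20))
    prof <- make_profile(scores)
    expect_equal(unname(pssm_features(prof)), oracle_pssm(scores, 4))
  }
  expect_length(pssm_features(make_profile(matrix(0, 6, 20))), 80L)
  expect_error(pssm_features(make_profile(matrix(0, 4, 20))), "length > 4")
})

test_that("disorder_features reports moments and run statistics with the 0 convention", {
  all_hi <- structure(list(id = "t", scores = rep(0.9, 30)), class = "disorder_track")
  v <- disorder_features(all_hi)
  expect_equal(unname(v), c(0.9, 0, 1, 0, 30, 30, 0, 0))

  all_lo <- structure(list(id = "t", scores = rep(0.1, 10)), class = "disorder_track")
  v2 <- disorder_features(all_lo)
  expect_equal(unname(v2[3:4]), c(0, 1))
  expect_equal(unname(v2[5:8]), c(0, 0, 10, 10))

  mixed <- structure(list(id = "t", scores = c(0.9, 0.9, 0.1, 0.9)),
                     class = "disorder_track")
  v3 <- disorder_features(mixed)
  expect_equal(unname(v3[3:8]), c(2, 1, 1, 2, 1, 1))
})

test_that("disorder and ss segment statistics match a run-length oracle", {
  for (s in c(2, 8, 14)) {
    scores <- withr_seed(s, runif(40))
    tr <- structure(list(id = "t", scores = scores), class = "disorder_track")
    v <- disorder_features(tr)
    dl <- oracle_segments(scores >= 0.5)
    nl <- oracle_segments(scores < 0.5)
    expect_equal(unname(v[3]), length(dl))
    expect_equal(unname(v[4]), length(nl))
    if (length(dl)) expect_equal(unname(v[5:6]), c(min(dl), max(dl)))
    if (length(nl)) expect_equal(unname(v[7:8]), c(min(nl), max(nl)))
  }
})

test_that("ss_features computes the documented 51 statistics", {
  rec <- protein_record("p", "ACDEFGHIW")
  tr <- structure(list(id = "p", states = "HHHEEECCC"), class = "ss_track")
  v <- ss_features(tr, rec)
  expect_length(v, 51L)
  expect_equal(unname(v[1:3]), rep(1 / 3, 3))          # state fractions
  expect_equal(unname(v[4:6]), rep(1 / 3, 3))          # segment shares
  seglen <- v[grepl("seglen", names(v))]
  expect_equal(unname(seglen[c("ssi.seglen.H.min", "ssi.seglen.H.max",
                               "ssi.seglen.H.mean", "ssi.seglen.H.sd")]),
               c(3, 3, 3, 0), ignore_attr = TRUE)
  # block (v) is a joint distribution over (group, state)
  expect_equal(sum(v[grepl("^ssi\\.gs\\.", names(v))]), 1)

  coil <- structure(list(id = "p", states = strrep("C", 9)), class = "ss_track")
  vc <- ss_features(coil, rec)
  expect_equal(unname(vc[1:3]), c(0, 0, 1))
  expect_equal(unname(vc[4:6]), c(0, 0, 1))
  expect_length(vc, 51L)

  short <- structure(list(id = "p", states = "HEC"), class = "ss_track")
  expect_error(ss_features(short, rec), "length")
})

test_that("ss distribution block reuses the positional variance statistic", {
  rec <- random_record(30, 3)
  states <- withr_seed(4, paste(sample(c("H", "E", "C"), 30, replace = TRUE),
                                collapse = ""))
  tr <- structure(list(id = rec$id, states = states), class = "ss_track")
  v <- ss_features(tr, rec)
  st <- strsplit(states, "")[[1]]
  for (s in c("H", "E", "C")) {
    pos <- which(st == s)
    expected <- if (length(pos) < 2) 0 else {
      d <- pos - pos[1]
      sum((d - mean(d))^2) / length(d)
    }
    expect_equal(v[[paste0("ssi.dist.", s)]], expected)
  }
})

test_that("domain vocabulary selection applies the min-count rule deterministically", {
  ann <- structure(list(p1 = c("D1", "D2"), p2 = c("D1"), p3 = c("D1", "D3")),
                   class = "domain_annotation")
  v <- build_domain_vocabulary(ann, c("p1", "p2", "p3"), min_count = 2)
  expect_equal(as.character(v), "D1")
  expect_length(build_domain_vocabulary(ann, c("p1", "p2", "p3"), min_count = 10), 0L)
  # count ties break by accession string
  ann2 <- structure(list(p1 = c("DB", "DA"), p2 = c("DB", "DA")),
                    class = "domain_annotation")
  v2 <- build_domain_vocabulary(ann2, c("p1", "p2"), min_count = 2)
  expect_equal(as.character(v2), c("DA", "DB"))
})

test_that("fdi_vector is the binary membership indicator over the vocabulary", {
  vocab <- domain_vocabulary(c("D1", "D2", "D3"))
  ann <- structure(list(p1 = "D1", p2 = c("D1", "D2", "D3", "D9")),
                   class = "domain_annotation")
  expect_equal(unname(fdi_vector("p1", ann, vocab)), c(1, 0, 0))
  expect_equal(unname(fdi_vector("p2", ann, vocab)), c(1, 1, 1))
  expect_equal(unname(fdi_vector("unknown", ann, vocab)), c(0, 0, 0))
})

test_that("encode_all assembles the canonical 315-feature vector and block subsets", {
  ds <- simulate_dataset(synth_config(2, 2, length_range = c(60, 80), seed = 31))
  rec <- ds$records[[1]]
  prof <- ds$profiles[[rec$id]]
  vocab <- domain_vocabulary(sprintf("IPR%06d", 1:17))
  full <- encode_all(rec, prof, encoder_config("all", vocabulary = vocab))
  expect_length(full, 315L)
  blocks <- table(factor(sub("\\..*", "", names(full)),
                         levels = c("ffg", "entropy", "dist", "trans", "pseaac",
                                    "dwt", "pssm", "diso", "ssi", "fdi")))
  expect_equal(unname(as.integer(blocks)), c(10, 2, 20, 45, 40, 42, 80, 8, 51, 17))

  expect_length(encode_all(rec, config = encoder_config("sequence")), 77L)
  expect_length(encode_all(rec, config = encoder_config("physicochemical")), 82L)
  expect_error(encode_all(rec, list(), encoder_config("evolutionary")), "pssm")
})

test_that("encode_dataset permutes rows with input order and nothing else", {
  ds <- simulate_dataset(synth_config(3, 3, length_range = c(60, 80), seed = 17))
  cfg <- encoder_config(c("sequence", "physicochemical"))
  fm1 <- encode_dataset(ds$records, ds$profiles, cfg, labels = ds$labels)
  perm <- c(4, 2, 6, 1, 3, 5)
  fm2 <- encode_dataset(ds$records[perm], ds$profiles, cfg, labels = ds$labels)
  expect_equal(fm2$x, fm1$x[perm, ])
  expect_equal(colnames(fm2$x), colnames(fm1$x))
  expect_equal(as.character(fm2$labels), as.character(fm1$labels)[perm])
})
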