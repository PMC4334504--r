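test_that("functional groups partition the amino-acid alphabet", {
  scheme <- functional_group_scheme()
  members <- unlist(scheme, use.names = FALSE)
  expect_length(members, 20L)
  expect_false(anyDuplicated(members) > 0)
  expect_setequal(members, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
})

test_that("ffg_frequencies counts by group and sums to one", {
  expect_equal(unname(ffg_frequencies(protein_record("p", "AAAA"))),
               c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1))
  v <- ffg_frequencies(protein_record("p", "FDHK"))
  expect_equal(unname(v), c(0.25, 0.25, 0.25, 0.25, 0, 0, 0, 0, 0, 0))
  v20 <- ffg_frequencies(protein_record("p", "ACDEFGHIKLMNPQRSTVWY"))
  expect_equal(unname(v20),
               c(0.15, 0.10, 0.05, 0.05, 0.05, 0.05, 0.05, 0.10, 0.10, 0.30))
  for (s in c(17, 23, 31)) {
    expect_equal(sum(ffg_frequencies(random_record(40, s))), 1)
  }
})

test_that("shannon entropies match closed forms and respect bounds", {
  expect_equal(unname(shannon_entropies(protein_record("p", "AAAA"))), c(0, 0))
  h <- shannon_entropies(protein_record("p", "ACDEFGHIKLMNPQRSTVWY"))
  expect_equal(unname(h[1]), log2(20))
  expect_equal(unname(shannon_entropies(protein_record("p", "ACAC"))[2]),
               -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3))
  expect_error(shannon_entropies(protein_record("p", "A")), "length >= 2")
  for (s in 1:5) {
    h <- shannon_entropies(random_record(60, s))
    expect_true(h[1] >= 0 && h[1] <= log2(20))
    expect_true(h[2] >= 0 && h[2] <= log2(400))
  }
})

test_that("distribution descriptor is the population variance of occurrence offsets", {
  d <- distribution_descriptor(protein_record("p", "AGA"))
  expect_equal(unname(d[c("dist.A", "dist.G")]), c(1.0, 0), ignore_attr = TRUE)
  expect_equal(distribution_descriptor(protein_record("p", "AAAA"))[["dist.A"]], 1.25)
  expect_equal(distribution_descriptor(protein_record("p", "AAAA"))[["dist.W"]], 0)
  for (s in c(7, 19)) {
    rec <- random_record(50, s)
    expect_equal(unname(distribution_descriptor(rec)),
                 oracle_distribution(rec$sequence))
  }
})

test_that("transition descriptor counts cross-group adjacencies over L", {
  expect_equal(sum(transition_descriptor(protein_record("p", "AAAA"))), 0)
  v <- transition_descriptor(protein_record("p", "DK"))
  expect_equal(v[["trans.carboxyl.primary_amine"]], 0.5)
  expect_equal(sum(v), 0.5)
  expect_equal(transition_descriptor(protein_record("p", "DKDK"))[["trans.carboxyl.primary_amine"]],
               0.75)
  for (s in c(3, 11)) {
    rec <- random_record(45, s)
    expect_equal(unname(transition_descriptor(rec)), oracle_transition(rec$sequence))
  }
})

test_that("pseaac matches its brute-force definition and normalizes to one", {
  hp <- pseaac(protein_record("p", strrep("A", 25)))
  expect_equal(hp[["pseaac.f.A"]], 1)
  expect_equal(sum(hp), 1)
  expect_equal(sum(abs(hp[-1])), 0)

  rec <- protein_record("p", "ACDEFGHIKLMNPQRSTVWYA")
  expect_equal(unname(pseaac(rec)), oracle_pseaac(rec$sequence))
  for (s in c(2, 9)) {
    rec <- random_record(35, s)
    v <- pseaac(rec)
    expect_length(v, 40L)
    expect_equal(sum(v), 1)
    expect_equal(unname(v), oracle_pseaac(rec$sequence))
  }
  expect_error(pseaac(protein_record("p", strrep("A", 20))), "length > 20")
})

test_that("dwt decomposition agrees with an independent convolution cascade", {
  x <- withr_seed(41, rnorm(64))
  mine <- dwt_decompose(x, 4)
  ref <- oracle_dwt(x, 4)
  expect_equal(mine$approximation, ref$approximation)
  for (l in 1:4) expect_equal(mine$details[[l]], ref$details[[l]])
})

test_that("dwt_features yields 42 named statistics, zero details on homopolymers", {
  v <- dwt_features(protein_record("p", strrep("G", 30)))
  expect_length(v, 42L)
  detail_stats <- v[grepl("cD", names(v))]
  expect_equal(max(abs(detail_stats)), 0)
  expect_equal(v[["dwt.hydrophobicity.raw.sd"]], 0)

  v2 <- dwt_features(random_record(80, 13))
  expect_length(v2, 42L)
  expect_error(dwt_features(protein_record("p", strrep("AC", 7))), "lower level")
})

test_that("encoders are pure: identical input gives bit-identical output", {
  rec <- random_record(70, 29)
  expect_identical(pseaac(rec), pseaac(rec))
  expect_identical(dwt_features(rec), dwt_features(rec))
  expect_identical(transition_descriptor(rec), transition_descriptor(rec))
})

test_that("property scales standardize to zero mean and unit population SD", {
  m <- property_scales()
  for (j in seq_len(ncol(m))) {
    expect_equal(mean(m[, j]), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(m[, j]^2)), 1, tolerance = 1e-9)
  }
})
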