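#' PSSM feature parameters
#'
#' @param lambda_max Largest positional lag (default 4). Must be smaller
#'   than the shortest admissible sequence length.
#' @return An object of class `pssm_params`.
#' @export
pssm_params <- function(lambda_max = 4L) {
  stopifnot(lambda_max >= 1L)
  structure(list(lambda_max = as.integer(lambda_max)), class = "pssm_params")
}

#' Evolutionary descriptors from a position-specific scoring matrix
#'
#' Every log-odds score is first squashed through the sigmoid
#' `f(x) = 1 / (1 + exp(-x))`; then for each amino-acid column i and lag
#' lambda = 1..`lambda_max`, the descriptor is the mean squared difference
#' between normalized scores lambda positions apart:
#' `theta_i^lambda = mean_j (E_{j,i} - E_{j+lambda,i})^2`. The output is
#' ordered lag-major (all 20 columns at lag 1, then lag 2, ...), 80
#' components at the default `lambda_max` of 4.
#'
#' @param profile A `pssm_profile` from [read_pssm()] with more rows than
#'   `lambda_max`.
#' @param params A [pssm_params()].
#' @return Named non-negative vector `pssm.theta.l<lambda>.<aa>`.
#' @export
pssm_features <- function(profile, params = pssm_params()) {
  L <- nrow(profile$scores)
  lmax <- params$lambda_max
  if (L <= lmax) {
    stop(sprintf("profile '%s': PSSM descriptors with lambda_max=%d need length > %d",
                 profile$id, lmax, lmax), call. = FALSE)
  }
  E <- 1 / (1 + exp(-profile$scores))
  out <- numeric(0)
  for (lam in seq_len(lmax)) {
    d <- E[1:(L - lam), , drop = FALSE] - E[(1 + lam):L, , drop = FALSE]
    th <- colMeans(d^2)
    names(th) <- paste0("pssm.theta.l", lam, ".", AA_ALPHABET)
    out <- c(out, th)
  }
  out
}

## Run-length segments of a logical vector: lengths of maximal TRUE runs.
run_lengths <- function(flag) {
  r <- rle(flag)
  r$lengths[r$values]
}

## min/max/mean/popSD of a length vector with the empty-class 0 convention.
segment_length_stats <- function(lens) {
  if (length(lens) == 0L) return(c(min = 0, max = 0, mean = 0, sd = 0))
  c(min = min(lens), max = max(lens), mean = mean(lens), sd = pop_sd(lens))
}

#' Disorder-track features
#'
#' Eight statistics of a per-residue disorder score track: mean and
#' population SD of the scores; the number of disorder and of non-disorder
#' segments (maximal runs of scores `>= threshold`, resp. `< threshold`);
#' and the minimum and maximum lengths of each segment class. A class with
#' no segments reports 0 for its length statistics.
#'
#' @param track A `disorder_track` from [read_disorder()].
#' @param threshold Disorder call cutoff (default 0.5, the conventional
#'   VSL2-style cutoff).
#' @return Named 8-vector `diso.*`.
#' @export
disorder_features <- function(track, threshold = 0.5) {
  s <- track$scores
  if (length(s) == 0L) stop("empty disorder track", call. = FALSE)
  dis <- s >= threshold
  dl <- run_lengths(dis)
  nl <- run_lengths(!dis)
  c(diso.mean = mean(s),
    diso.sd = pop_sd(s),
    diso.n_disorder_segments = length(dl),
    diso.n_order_segments = length(nl),
    diso.disorder_len_min = if (length(dl)) min(dl) else 0,
    diso.disorder_len_max = if (length(dl)) max(dl) else 0,
    diso.order_len_min = if (length(nl)) min(nl) else 0,
    diso.order_len_max = if (length(nl)) max(nl) else 0)
}

#' Secondary-structure features
#'
#' Fifty-one statistics of a three-state (helix H, strand E, coil C)
#' secondary-structure string paired with its sequence: (i) per-state
#' residue fractions (3); (ii) per-state segment counts divided by the
#' total segment count (3); (iii) the positional distribution statistic
#' (population variance of occurrence distances from the first occurrence,
#' as in [distribution_descriptor()]) of each state (3); (iv) min, max,
#' mean and population SD of segment lengths per state, 0 when a state is
#' absent (12); (v) the joint frequency of (functional group, state) pairs,
#' count divided by sequence length, group-major (30). Block (v) sums to 1
#' because every residue has exactly one group and one state.
#'
#' @param track An `ss_track` from [read_ss2()], same length as the
#'   sequence.
#' @param record The matching [protein_record()].
#' @param scheme Functional-group scheme.
#' @return Named 51-vector `ssi.*`.
#' @export
ss_features <- function(track, record, scheme = functional_group_scheme()) {
  st <- strsplit(track$states, "", fixed = TRUE)[[1L]]
  chars <- seq_chars(record)
  L <- length(chars)
  if (length(st) != L) {
    stop(sprintf("record '%s': secondary-structure length %d != sequence length %d",
                 record$id, length(st), L), call. = FALSE)
  }
  frac <- vapply(SS_STATES, function(s) sum(st == s), numeric(1L)) / L
  names(frac) <- paste0("ssi.frac.", SS_STATES)

  r <- rle(st)
  n_seg_total <- length(r$lengths)
  segshare <- vapply(SS_STATES, function(s) sum(r$values == s), numeric(1L)) / n_seg_total
  names(segshare) <- paste0("ssi.segshare.", SS_STATES)

  dist <- vapply(SS_STATES, function(s) {
    pos <- which(st == s)
    if (length(pos) <= 1L) return(0)
    pop_var(pos - pos[1L])
  }, numeric(1L))
  names(dist) <- paste0("ssi.dist.", SS_STATES)

  seglen <- numeric(0)
  for (s in SS_STATES) {
    stats <- segment_length_stats(r$lengths[r$values == s])
    names(stats) <- paste0("ssi.seglen.", s, ".", names(stats))
    seglen <- c(seglen, stats)
  }

  gmap <- group_of_residue(scheme)
  groups <- gmap[chars]
  gs <- numeric(0)
  for (g in names(scheme)) {
    for (s in SS_STATES) {
      v <- sum(groups == g & st == s) / L
      names(v) <- paste0("ssi.gs.", g, ".", s)
      gs <- c(gs, v)
    }
  }
  c(frac, segshare, dist, seglen, gs)
}

#' Build a functional-domain vocabulary from positive-class annotations
#'
#' Selects the domain accessions annotated on at least `min_count` distinct
#' positive proteins. The vocabulary order is fixed at construction
#' (descending positive count, ties broken by accession string) and is
#' serialized with any model that uses it.
#'
#' @param annotations A `domain_annotation` from [read_domains()].
#' @param positive_ids Ids of the positive-class proteins.
#' @param min_count Minimum number of distinct positive proteins carrying
#'   the accession (default 25).
#' @return An object of class `domain_vocabulary`: a character vector of
#'   accessions with attributes `min_count` and `n_positive`.
#' @export
build_domain_vocabulary <- function(annotations, positive_ids, min_count = 25L) {
  if (length(positive_ids) == 0L) stop("positive_ids must be non-empty", call. = FALSE)
  accs <- unlist(lapply(positive_ids, function(id) domain_set(annotations, id)),
                 use.names = FALSE)
  if (length(accs) == 0L) return(domain_vocabulary(character(0), min_count, length(positive_ids)))
  counts <- table(accs)
  keep <- counts[counts >= min_count]
  ord <- order(-as.numeric(keep), names(keep))
  domain_vocabulary(names(keep)[ord], min_count, length(positive_ids))
}

#' @rdname build_domain_vocabulary
#' @param accessions Ordered accession strings (no duplicates).
#' @param n_positive Size of the positive set the vocabulary was derived
#'   from (provenance only).
#' @export
domain_vocabulary <- function(accessions, min_count = NA_integer_, n_positive = NA_integer_) {
  accessions <- as.character(accessions)
  if (anyDuplicated(accessions)) stop("duplicate accession in vocabulary", call. = FALSE)
  structure(accessions, min_count = min_count, n_positive = n_positive,
            class = "domain_vocabulary")
}

#' Binary functional-domain indicator vector
#'
#' @param protein_id Protein id.
#' @param annotations A `domain_annotation`.
#' @param vocabulary A [domain_vocabulary()].
#' @return Named 0/1 vector `fdi.<accession>`, one component per vocabulary
#'   entry; proteins absent from the annotation map yield all zeros.
#' @export
fdi_vector <- function(protein_id, annotations, vocabulary) {
  present <- as.character(vocabulary) %in% domain_set(annotations, protein_id)
  out <- as.numeric(present)
  names(out) <- paste0("fdi.", as.character(vocabulary))
  out
}

FEATURE_BLOCKS <- c("ffg", "entropy", "distribution", "transition",
                    "pseaac", "dwt", "pssm", "disorder", "ssi", "fdi")

#' Encoder configuration
#'
#' Bundles every tunable of the feature encoding: which blocks to compute
#' (in the canonical order ffg, entropy, distribution, transition, pseaac,
#' dwt, pssm, disorder, ssi, fdi), the property scales, the PseAAC, DWT and
#' PSSM parameters, the disorder threshold and the domain vocabulary.
#' Convenience block sets: `"sequence"` (ffg + entropy + distribution +
#' transition, 77 features), `"physicochemical"` (pseaac + dwt, 82),
#' `"evolutionary"` (pssm, 80), `"structural"` (disorder + ssi + fdi).
#'
#' @param blocks Blocks to encode; block names, category names or `"all"`.
#' @param scales Property matrix from [property_scales()].
#' @param pseaac A [pseaac_params()].
#' @param dwt A [dwt_params()].
#' @param pssm A [pssm_params()].
#' @param disorder_threshold Disorder call cutoff.
#' @param vocabulary A [domain_vocabulary()] (required when the fdi block
#'   is encoded).
#' @param scheme Functional-group scheme.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(blocks = "all", scales = property_scales(),
                           pseaac = pseaac_params(), dwt = dwt_params(),
                           pssm = pssm_params(), disorder_threshold = 0.5,
                           vocabulary = NULL, scheme = functional_group_scheme()) {
  categories <- list(
    all = FEATURE_BLOCKS,
    sequence = c("ffg", "entropy", "distribution", "transition"),
    physicochemical = c("pseaac", "dwt"),
    evolutionary = "pssm",
    structural = c("disorder", "ssi", "fdi")
  )
  expanded <- unlist(lapply(blocks, function(b) {
    if (b %in% names(categories)) categories[[b]] else b
  }), use.names = FALSE)
  if (!all(expanded %in% FEATURE_BLOCKS)) {
    stop(sprintf("unknown block '%s'", setdiff(expanded, FEATURE_BLOCKS)[1L]), call. = FALSE)
  }
  ## canonical order regardless of request order
  expanded <- FEATURE_BLOCKS[FEATURE_BLOCKS %in% expanded]
  if ("fdi" %in% expanded && is.null(vocabulary)) {
    stop("encoding the fdi block requires a domain vocabulary", call. = FALSE)
  }
  structure(list(blocks = expanded, scales = scales, pseaac = pseaac,
                 dwt = dwt, pssm = pssm,
                 disorder_threshold = disorder_threshold,
                 vocabulary = vocabulary, scheme = scheme),
            class = "encoder_config")
}

#' Encode one protein as a named feature vector
#'
#' Concatenates the requested feature blocks in the canonical order. With
#' the full configuration and a 17-entry domain vocabulary the vector has
#' 10 + 2 + 20 + 45 + 40 + 42 + 80 + 8 + 51 + 17 = 315 components.
#'
#' @param record A [protein_record()].
#' @param profiles List of auxiliary profiles for this protein: elements
#'   `pssm` (`pssm_profile`), `ss` (`ss_track`), `disorder`
#'   (`disorder_track`) and `domains` (character vector of accessions), as
#'   needed by the requested blocks.
#' @param config An [encoder_config()].
#' @return Named numeric vector.
#' @export
encode_all <- function(record, profiles = list(), config = encoder_config()) {
  L <- nchar(record$sequence)
  need <- function(name, cls) {
    p <- profiles[[name]]
    if (is.null(p) || !inherits(p, cls)) {
      stop(sprintf("record '%s': block requires a %s profile ('%s')",
                   record$id, cls, name), call. = FALSE)
    }
    p
  }
  parts <- list()
  for (block in config$blocks) {
    parts[[block]] <- switch(block,
      ffg = ffg_frequencies(record, config$scheme),
      entropy = shannon_entropies(record),
      distribution = distribution_descriptor(record),
      transition = transition_descriptor(record, config$scheme),
      pseaac = pseaac(record, config$pseaac, config$scales),
      dwt = dwt_features(record, config$dwt, config$scales),
      pssm = {
        p <- need("pssm", "pssm_profile")
        if (nrow(p$scores) != L) {
          stop(sprintf("record '%s': pssm block length %d != sequence length %d",
                       record$id, nrow(p$scores), L), call. = FALSE)
        }
        pssm_features(p, config$pssm)
      },
      disorder = {
        p <- need("disorder", "disorder_track")
        if (length(p$scores) != L) {
          stop(sprintf("record '%s': disorder block length %d != sequence length %d",
                       record$id, length(p$scores), L), call. = FALSE)
        }
        disorder_features(p, config$disorder_threshold)
      },
      ssi = ss_features(need("ss", "ss_track"), record, config$scheme),
      fdi = {
        dom <- profiles$domains
        if (is.null(dom)) dom <- character(0)
        ann <- structure(stats::setNames(list(dom), record$id), class = "domain_annotation")
        fdi_vector(record$id, ann, config$vocabulary)
      }
    )
  }
  ## element names already carry their block prefix; drop the list names so
  ## unlist() does not prepend them a second time
  unlist(unname(parts))
}

#' Encode a dataset into a feature matrix
#'
#' @param records List of [protein_record()].
#' @param profiles Named list (by protein id) of per-protein profile lists
#'   as accepted by [encode_all()]; may be empty for sequence-only blocks.
#' @param config An [encoder_config()].
#' @param labels Optional named vector (by protein id) or unnamed vector in
#'   record order, over \{"positive", "negative"\}.
#' @return A [feature_matrix()].
#' @export
encode_dataset <- function(records, profiles = list(), config = encoder_config(),
                           labels = NULL) {
  ids <- vapply(records, `[[`, character(1L), "id")
  rows <- lapply(records, function(rec) {
    encode_all(rec, profiles[[rec$id]], config)
  })
  nm <- names(rows[[1L]])
  for (r in rows) {
    if (!identical(names(r), nm)) stop("inconsistent feature names across records", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  if (!is.null(labels) && !is.null(names(labels))) labels <- labels[ids]
  feature_matrix(m, labels)
}
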