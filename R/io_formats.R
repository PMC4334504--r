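#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into validated [protein_record()] objects. Sequences
#' are upper-cased; any character outside the 20 standard amino acids (for
#' example the ambiguity codes B, J, O, U, X, Z) is a parse error naming the
#' record and position, because downstream encoders are only defined on the
#' 20-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @return List of `protein_record`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L) return(list())
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop(sprintf("FASTA '%s': entry with empty header", path), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("FASTA '%s': duplicate id '%s'", path, ids[anyDuplicated(ids)]), call. = FALSE)
  }
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    records[[i]] <- protein_record(ids[i], as.character(set[[i]]))
  }
  records
}

#' Write protein records to a FASTA file
#'
#' @param records List of [protein_record()].
#' @param path Output path.
#' @param width Line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(paste0(">", rec$id), con)
    s <- rec$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Length-filter a protein dataset
#'
#' Screens out sequences shorter than `min_len` or longer than `max_len`
#' residues (both bounds inclusive for keeping), the standard sanitation
#' step before feature extraction. Filtering is not failure: dropped records
#' are returned alongside a machine-readable reason.
#'
#' @param records List of [protein_record()].
#' @param min_len,max_len Inclusive length bounds (defaults 50 and 3000).
#' @return List with `kept` (records within bounds, input order) and
#'   `dropped` (data frame with columns `id`, `length`, `reason`).
#' @export
sanitize_dataset <- function(records, min_len = 50L, max_len = 3000L) {
  lens <- vapply(records, function(r) nchar(r$sequence), integer(1L))
  too_short <- lens < min_len
  too_long <- lens > max_len
  keep <- !(too_short | too_long)
  dropped <- data.frame(
    id = vapply(records[!keep], `[[`, character(1L), "id"),
    length = lens[!keep],
    reason = ifelse(too_short[!keep],
                    sprintf("shorter than %d residues", min_len),
                    sprintf("longer than %d residues", max_len)),
    stringsAsFactors = FALSE
  )
  list(kept = records[keep], dropped = dropped)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the classic PSI-BLAST `-Q` ASCII matrix: header lines, then one
#' row per residue carrying the position index, the query residue, and the
#' 20-column log-odds block (any trailing percentage block is ignored — the
#' descriptors use scores, not frequencies).
#'
#' @param path Path to the PSSM file.
#' @param id Profile identifier; defaults to the file name without extension.
#' @return An object of class `pssm_profile` with elements `id`, `residues`
#'   (query sequence echoed by the file) and `scores` (L x 20 numeric
#'   matrix, columns in the amino-acid order of the file header).
#' @export
read_pssm <- function(path, id = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path)
  tok <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1L]])
  ## Header row: 20 (or 40) single-letter amino-acid column labels.
  is_aa_header <- vapply(tok, function(t) {
    length(t) >= 20L && all(nchar(t) == 1L) && all(t %in% AA_ALPHABET)
  }, logical(1L))
  hdr <- which(is_aa_header)
  if (length(hdr) == 0L) {
    stop(sprintf("PSSM '%s': no amino-acid column header found", path), call. = FALSE)
  }
  col_order <- tok[[hdr[1L]]][1:20]
  is_data <- vapply(tok, function(t) {
    length(t) >= 2L && grepl("^[0-9]+$", t[1L]) && grepl("^[A-Z]$", t[2L])
  }, logical(1L))
  rows <- which(is_data)
  rows <- rows[rows > hdr[1L]]
  if (length(rows) == 0L) stop(sprintf("PSSM '%s': no data rows", path), call. = FALSE)
  scores <- matrix(NA_real_, nrow = length(rows), ncol = 20L,
                   dimnames = list(NULL, col_order))
  residues <- character(length(rows))
  for (k in seq_along(rows)) {
    t <- tok[[rows[k]]]
    if (length(t) < 22L) {
      stop(sprintf("PSSM '%s' line %d: expected 20 numeric log-odds values",
                   path, rows[k]), call. = FALSE)
    }
    residues[k] <- t[2L]
    vals <- suppressWarnings(as.numeric(t[3:22]))
    if (anyNA(vals)) {
      stop(sprintf("PSSM '%s' line %d: expected 20 numeric log-odds values",
                   path, rows[k]), call. = FALSE)
    }
    scores[k, ] <- vals
  }
  ## Reorder columns to the canonical alphabet so all profiles are comparable.
  scores <- scores[, AA_ALPHABET, drop = FALSE]
  structure(list(id = id, residues = paste(residues, collapse = ""),
                 scores = scores),
            class = "pssm_profile")
}

#' Write a PSSM profile in PSI-BLAST ASCII layout
#'
#' @param profile A `pssm_profile` (see [read_pssm()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  writeLines(paste0("    ", paste(sprintf("%3s", AA_ALPHABET), collapse = " ")), con)
  res <- strsplit(profile$residues, "", fixed = TRUE)[[1L]]
  for (i in seq_along(res)) {
    writeLines(paste0(
      sprintf("%4d %s ", i, res[i]),
      paste(sprintf("%3d", as.integer(round(profile$scores[i, ]))), collapse = " ")
    ), con)
  }
  invisible(path)
}

#' Read a PSIPRED-style secondary-structure file (.ss2, VFORMAT)
#'
#' Expects the PSIPRED vertical format: optional comment/blank lines, then
#' one row per residue with index, residue, state (H/E/C) and three state
#' probabilities.
#'
#' @param path Path to the .ss2 file.
#' @param id Track identifier; defaults to the file name without extension.
#' @return An object of class `ss_track` with elements `id` and `states`
#'   (string over H/E/C).
#' @export
read_ss2 <- function(path, id = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  states <- character(0)
  for (ln in which(keep)) {
    t <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(t) != 6L) {
      stop(sprintf("ss2 '%s' line %d: expected 6 columns (index, residue, state, 3 probabilities)",
                   path, ln), call. = FALSE)
    }
    if (!t[3L] %in% SS_STATES) {
      stop(sprintf("ss2 '%s' line %d: state '%s' not in {H,E,C}", path, ln, t[3L]), call. = FALSE)
    }
    states <- c(states, t[3L])
  }
  if (length(states) == 0L) stop(sprintf("ss2 '%s': no data rows", path), call. = FALSE)
  structure(list(id = id, states = paste(states, collapse = "")), class = "ss_track")
}

#' @rdname read_ss2
#' @param track An `ss_track`.
#' @param probs Optional L x 3 matrix of state probabilities (columns C, H,
#'   E as in PSIPRED); a one-hot encoding of the states is written when
#'   omitted.
#' @export
write_ss2 <- function(track, path, probs = NULL) {
  st <- strsplit(track$states, "", fixed = TRUE)[[1L]]
  if (is.null(probs)) {
    probs <- cbind(C = as.numeric(st == "C"), H = as.numeric(st == "H"),
                   E = as.numeric(st == "E"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# PSIPRED VFORMAT", ""), con)
  for (i in seq_along(st)) {
    writeLines(sprintf("%4d %s %s  %5.3f %5.3f %5.3f",
                       i, "X", st[i], probs[i, 1L], probs[i, 2L], probs[i, 3L]), con)
  }
  invisible(path)
}

#' Read a per-residue disorder score track
#'
#' Tab/space separated rows of index, residue, score; scores must lie in
#' \[0, 1\].
#'
#' @param path Path to the disorder file.
#' @param id Track identifier; defaults to the file name without extension.
#' @return An object of class `disorder_track` with elements `id` and
#'   `scores` (numeric vector in \[0, 1\]).
#' @export
read_disorder <- function(path, id = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  scores <- numeric(0)
  for (ln in which(keep)) {
    t <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(t) != 3L) {
      stop(sprintf("disorder '%s' line %d: expected 3 columns (index, residue, score)",
                   path, ln), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(t[3L]))
    if (is.na(v)) {
      stop(sprintf("disorder '%s' line %d: non-numeric score '%s'", path, ln, t[3L]),
           call. = FALSE)
    }
    if (v < 0 || v > 1) {
      stop(sprintf("disorder '%s' line %d: score %g outside [0, 1]", path, ln, v),
           call. = FALSE)
    }
    scores <- c(scores, v)
  }
  if (length(scores) == 0L) stop(sprintf("disorder '%s': no data rows", path), call. = FALSE)
  structure(list(id = id, scores = scores), class = "disorder_track")
}

#' @rdname read_disorder
#' @param track A `disorder_track`.
#' @param residues Optional residue string echoed into column 2.
#' @export
write_disorder <- function(track, path, residues = NULL) {
  n <- length(track$scores)
  res <- if (is.null(residues)) rep("X", n) else strsplit(residues, "", fixed = TRUE)[[1L]]
  writeLines(sprintf("%d\t%s\t%s", seq_len(n), res,
                     formatC(track$scores, format = "f", digits = 4)), path)
  invisible(path)
}

#' Read and write protein-to-domain annotation tables
#'
#' A two-column TSV mapping protein id to domain accession (one pair per
#' row, repeated ids allowed). Proteins absent from the table have an empty
#' annotation set.
#'
#' @param path Path to the TSV file.
#' @return `read_domains`: an object of class `domain_annotation` — a named
#'   list of character vectors of accessions.
#' @export
read_domains <- function(path) {
  ann <- list()
  if (file.exists(path) && file.size(path) > 0L) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("protein_id", "accession"),
                            colClasses = "character", quote = "")
    if (nrow(df) > 0L) {
      ann <- lapply(split(df$accession, df$protein_id), function(a) sort(unique(a)))
    }
  }
  structure(ann, class = "domain_annotation")
}

#' @rdname read_domains
#' @param annotation A `domain_annotation`.
#' @export
write_domains <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(annotation)) {
    for (acc in annotation[[id]]) writeLines(paste(id, acc, sep = "\t"), con)
  }
  invisible(path)
}

#' Accessions annotated on one protein
#'
#' @param annotation A `domain_annotation`.
#' @param id Protein id; unknown ids yield an empty set.
#' @return Character vector of accessions.
#' @export
domain_set <- function(annotation, id) {
  if (id %in% names(annotation)) annotation[[id]] else character(0)
}

#' Construct a feature matrix
#'
#' The container every downstream stage consumes: an n x d numeric matrix
#' with unique feature names and sample ids, plus optional binary labels.
#'
#' @param x Numeric matrix with rownames (sample ids) and colnames (feature
#'   names). No missing values allowed.
#' @param labels Optional vector over \{"positive", "negative"\} of length
#'   `nrow(x)`.
#' @return An object of class `feature_matrix` with elements `x` and
#'   `labels` (factor with levels positive/negative, or `NULL`).
#' @export
feature_matrix <- function(x, labels = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("feature matrix needs sample ids (rownames) and feature names (colnames)",
         call. = FALSE)
  }
  dup <- anyDuplicated(colnames(x))
  if (dup) {
    stop(sprintf("duplicate feature name '%s'", colnames(x)[dup]), call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate sample ids", call. = FALSE)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  if (!is.null(labels)) {
    if (length(labels) != nrow(x)) stop("labels length must equal row count", call. = FALSE)
    labels <- as.character(labels)
    if (!all(labels %in% c("positive", "negative"))) {
      stop("labels must be 'positive' or 'negative'", call. = FALSE)
    }
    labels <- factor(labels, levels = c("positive", "negative"))
  }
  structure(list(x = x, labels = labels), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features%s\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$labels)) "" else
                sprintf(" (%d positive / %d negative)",
                        sum(x$labels == "positive"), sum(x$labels == "negative"))))
  invisible(x)
}

#' Read and write feature matrices as CSV
#'
#' CSV layout: header row; first column `id`; optional `label` column;
#' remaining columns numeric features. Values are written with 10
#' significant digits, so write-then-read is exact for values already at
#' that precision.
#'
#' @param path CSV path.
#' @return `read_feature_matrix`: a [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "id") {
    stop(sprintf("feature CSV '%s': first column must be 'id'", path), call. = FALSE)
  }
  ids <- as.character(df$id)
  labels <- NULL
  feat_cols <- setdiff(names(df), "id")
  if ("label" %in% feat_cols) {
    labels <- df$label
    feat_cols <- setdiff(feat_cols, "label")
  }
  m <- as.matrix(df[, feat_cols, drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("feature CSV '%s': non-numeric feature values", path),
                           call. = FALSE)
  rownames(m) <- ids
  feature_matrix(m, labels)
}

#' @rdname read_feature_matrix
#' @param fm A [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  vals <- apply(fm$x, 2L, function(col) sprintf("%.10g", col))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(fm$x))
  df <- data.frame(id = rownames(fm$x), stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(fm$labels)) df$label <- as.character(fm$labels)
  df <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE))
  names(df) <- c("id", if (!is.null(fm$labels)) "label", colnames(fm$x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save and load a trained ensemble model
#'
#' The model archive is a directory holding `config.json` (feature list,
#' vote rule, seed, member count) and one serialized forest per ensemble
#' member, so a saved model reloads to identical predictions.
#'
#' @param model An `ensemble_model` from [train_ensemble()].
#' @param path Directory to create or overwrite.
#' @return `save_model`: `path`, invisibly. `load_model`: the restored
#'   `ensemble_model`.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(features = model$features, seed = model$seed,
               tie_rule = model$tie_rule, k = length(model$members),
               rf_params = model$rf_params)
  jsonlite::write_json(meta, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (k in seq_along(model$members)) {
    saveRDS(model$members[[k]], file.path(path, sprintf("member_%02d.rds", k)))
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  cfg_path <- file.path(path, "config.json")
  if (!file.exists(cfg_path)) stop(sprintf("no model config at %s", cfg_path), call. = FALSE)
  meta <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  members <- lapply(seq_len(meta$k), function(k) {
    readRDS(file.path(path, sprintf("member_%02d.rds", k)))
  })
  structure(list(members = members, features = meta$features,
                 seed = meta$seed, tie_rule = meta$tie_rule,
                 rf_params = as.list(meta$rf_params)),
            class = "ensemble_model")
}
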