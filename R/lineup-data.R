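#' Lineup design
#'
#' Describes the shape of a sequential lineup experiment: the number of faces
#' shown one at a time (`I`) and the number of confidence levels attached to
#' "yes" responses (`K`). `K = 1` means binary yes/no judgments only.
#'
#' @param I Number of faces per lineup (sequence length), a positive integer.
#' @param K Number of confidence levels per "yes" response, a positive
#'   integer. Confidence bins are ordered from lowest to highest confidence.
#' @return An object of class `lineup_design` with elements `I` and `K`.
#' @examples
#' lineup_design(6)        # binary six-face lineup
#' lineup_design(6, K = 4) # four confidence levels per "yes"
#' @export
lineup_design <- function(I, K = 1L) {
  I <- as.integer(I); K <- as.integer(K)
  if (length(I) != 1L || is.na(I) || I < 1L)
    stop("'I' must be a single integer >= 1")
  if (length(K) != 1L || is.na(K) || K < 1L)
    stop("'K' must be a single integer >= 1")
  structure(list(I = I, K = K), class = "lineup_design")
}

#' @export
print.lineup_design <- function(x, ...) {
  cat(sprintf("Sequential lineup design: I = %d faces, K = %d confidence level%s\n",
              x$I, x$K, if (x$K > 1L) "s" else " (binary)"))
  invisible(x)
}

# Canonical labels ---------------------------------------------------------

#' Category and condition labels for a design
#'
#' Response categories are "yes@i" for each sequence position (split into
#' ":binK" suffixes when `K > 1`, ordered low to high confidence) followed by
#' a single "reject" category. Conditions are "tp1".."tpI" (target present at
#' the given position) followed by "ta" (target absent).
#'
#' @param design A [lineup_design()].
#' @return Character vector of labels.
#' @keywords internal
category_labels <- function(design) {
  if (design$K == 1L) {
    c(paste0("yes@", seq_len(design$I)), "reject")
  } else {
    c(as.vector(t(outer(seq_len(design$I), seq_len(design$K),
                        function(i, k) paste0("yes@", i, ":bin", k)))),
      "reject")
  }
}

#' @rdname category_labels
#' @keywords internal
condition_labels <- function(design) {
  c(paste0("tp", seq_len(design$I)), "ta")
}

# Condition helpers: conditions are encoded as target position 1..I, or NA
# for target-absent, throughout the package.
target_position_of <- function(condition, I) {
  if (is.character(condition)) {
    if (condition == "ta") return(NA_integer_)
    h <- suppressWarnings(as.integer(sub("^tp", "", condition)))
    if (is.na(h) || h < 1L || h > I) stop("unknown condition label: ", condition)
    return(h)
  }
  if (is.na(condition)) return(NA_integer_)
  h <- as.integer(condition)
  if (h < 1L || h > I) stop("target position must lie in 1..I or be NA (absent)")
  h
}

#' Censored sequential-lineup frequency table
#'
#' Bundles a count matrix of censored lineup responses with its design. Rows
#' are response categories ("yes@i", optionally split into confidence bins,
#' plus "reject"); columns are lineup conditions ("tp1".."tpI", "ta").
#'
#' @param counts Integer matrix, `(I*K + 1)` rows by `(I + 1)` columns, of
#'   nonnegative response frequencies. Row/column names, if present, must
#'   match the canonical labels.
#' @param design A [lineup_design()].
#' @return An object of class `lineup_table` with elements `design`, `counts`
#'   and `condition_totals`.
#' @seealso [builtin_table()], [read_lineup_table()], [outcome_summary()],
#'   [hazard_differences()]
#' @export
lineup_table <- function(counts, design) {
  stopifnot(inherits(design, "lineup_design"))
  counts <- as.matrix(counts)
  n_cat <- design$I * design$K + 1L
  n_cond <- design$I + 1L
  if (nrow(counts) != n_cat || ncol(counts) != n_cond)
    stop(sprintf("counts must be %d categories x %d conditions, got %d x %d",
                 n_cat, n_cond, nrow(counts), ncol(counts)))
  if (any(is.na(counts)))
    stop("counts contain missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("counts must be nonnegative integers; offending cell: row %d ('%s'), column %d ('%s')",
                 bad[1L, 1L], category_labels(design)[bad[1L, 1L]],
                 bad[1L, 2L], condition_labels(design)[bad[1L, 2L]]))
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(category_labels(design), condition_labels(design))
  structure(list(design = design, counts = counts,
                 condition_totals = colSums(counts)),
            class = "lineup_table")
}

#' @export
print.lineup_table <- function(x, ...) {
  cat(sprintf("Censored sequential lineup table (I = %d, K = %d), N = %d\n",
              x$design$I, x$design$K, sum(x$counts)))
  print(cbind(x$counts, Total = rowSums(x$counts)))
  cat("Condition totals:", paste(x$condition_totals, collapse = ", "), "\n")
  invisible(x)
}

#' Read a lineup table from CSV
#'
#' The expected dialect has a first column of category labels ("yes@1",
#' optionally suffixed ":binK", then "reject") and one column per condition
#' named "tp1".."tpI" and "ta", with integer cells.
#'
#' @param source Path to a CSV file.
#' @param design A [lineup_design()] the file must conform to.
#' @return A validated [lineup_table()].
#' @export
read_lineup_table <- function(source, design) {
  df <- utils::read.csv(source, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != design$I + 2L)
    stop(sprintf("expected %d columns (category + %d conditions), found %d",
                 design$I + 2L, design$I + 1L, ncol(df)))
  want_cond <- condition_labels(design)
  got_cond <- names(df)[-1L]
  if (!identical(got_cond, want_cond))
    stop("malformed header: condition columns must be ",
         paste(want_cond, collapse = ", "), " in order; found ",
         paste(got_cond, collapse = ", "))
  want_cat <- category_labels(design)
  if (!identical(as.character(df[[1L]]), want_cat))
    stop("malformed category column: expected ",
         paste(want_cat, collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("counts must parse as numbers; check for stray text cells")
  rownames(m) <- want_cat
  lineup_table(m, design)
}

#' Write a lineup table to CSV
#'
#' Writes the canonical dialect read by [read_lineup_table()]; reading the
#' file back reproduces the table exactly.
#'
#' @param table A [lineup_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lineup_table <- function(table, path) {
  stopifnot(inherits(table, "lineup_table"))
  df <- data.frame(category = rownames(table$counts), table$counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published sequential lineup frequency tables
#'
#' The binary (K = 1) choice-frequency tables from the two large six-face
#' sequential lineup experiments analysed throughout this package: the Wilson
#' et al. study (no stopping rule enforced during collection; the stopping
#' rule is emulated by censoring at the first "yes") and the Dunn et al.
#' study (actual stopping rule, target-present conditions oversampled
#' roughly 4:1).
#'
#' In the Dunn table the published column total for target position 6 (938)
#' differs by one from the sum of the published cells (939); the cells are
#' taken as authoritative and totals are always derived from them.
#'
#' @param study `"wilson"` or `"dunn"`.
#' @return A [lineup_table()] with I = 6, K = 1.
#' @examples
#' w <- builtin_table("wilson")
#' w$condition_totals  # 709 696 691 699 696 701 4151
#' @export
builtin_table <- function(study = c("wilson", "dunn")) {
  study <- match.arg(study)
  path <- system.file("extdata", paste0(study, "_table1.csv"),
                      package = "seqsdt", mustWork = TRUE)
  read_lineup_table(path, lineup_design(6L))
}

#' Outcome proportions of a lineup procedure
#'
#' Collapses a binary lineup table into the six forensic outcome
#' proportions: in target-present lineups a hit (`TP1`, "yes" to the target),
#' a known-lure false alarm (`TP2`) or a miss (`TP3`, "reject all"); in
#' target-absent lineups a known-lure false alarm (`TA1`), an
#' innocent-suspect false alarm (`TA2`) or a correct rejection (`TA3`).
#' Target positions are treated as equiprobable, so target-present
#' proportions are unweighted means of the per-position rates (with equal
#' condition totals this coincides with pooling the counts).
#' Target-absent lineups contain one designated innocent suspect among the
#' `I` members, so the total "yes" rate splits as `TA2 = rate / I` and
#' `TA1 = rate * (I - 1) / I`.
#'
#' @param table A binary (K = 1) [lineup_table()].
#' @return An object of class `outcome_summary`: a named numeric vector with
#'   elements TP1..TP3 and TA1..TA3, each triple summing to 1.
#' @examples
#' round(100 * unclass(outcome_summary(builtin_table("wilson"))), 1)
#' @export
outcome_summary <- function(table) {
  stopifnot(inherits(table, "lineup_table"))
  if (table$design$K != 1L)
    stop("outcome_summary() is defined for binary (K = 1) tables")
  I <- table$design$I
  cnt <- table$counts
  tp <- cnt[, seq_len(I), drop = FALSE]
  ta <- cnt[, I + 1L]
  n_h <- colSums(tp)
  use <- n_h > 0 # empty target-present conditions carry no information
  hit_rate <- (tp[cbind(seq_len(I), seq_len(I))] / n_h)[use]
  reject_rate <- (tp[I + 1L, ] / n_h)[use]
  lure_rate <- 1 - hit_rate - reject_rate
  ta_yes_rate <- sum(ta[seq_len(I)]) / sum(ta)
  out <- c(TP1 = mean(hit_rate),
           TP2 = mean(lure_rate),
           TP3 = mean(reject_rate),
           TA1 = ta_yes_rate * (I - 1) / I,
           TA2 = ta_yes_rate / I,
           TA3 = unname(ta[I + 1L]) / sum(ta))
  structure(out, class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, digits = 3, ...) {
  cat("Outcome proportions (target-present / target-absent):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Target-rejection hazard contrasts
#'
#' For each target position `h` and later sequence position `i > h`,
#' contrasts the discrete hazard of a "yes" to a lure at position `i` -- the
#' conditional probability of an identification given that the lineup
#' reached position `i` -- between target-present lineups in which the
#' target was rejected at `h` and target-absent lineups. Under models in
#' which rejecting the target does not move the criterion, the difference is
#' zero for every pair; a conservative shift after target rejection makes
#' all differences negative.
#'
#' @param table A binary (K = 1) [lineup_table()].
#' @return An `I-1` by `I-1` matrix with rows `h = 1..I-1`, columns
#'   `i = 2..I`; entries with `i <= h` are structurally `NA`, and entries
#'   whose conditional denominator is zero are `NaN` (flagged undefined
#'   rather than silently zero).
#' @examples
#' hazard_differences(builtin_table("wilson"))["h=1", "i=2"] # ~ -0.144
#' @export
hazard_differences <- function(table) {
  stopifnot(inherits(table, "lineup_table"))
  if (table$design$K != 1L)
    stop("hazard_differences() is defined for binary (K = 1) tables")
  I <- table$design$I
  cnt <- table$counts
  tot <- table$condition_totals
  # remaining(c, i): witnesses whose lineup reached position i in condition c
  remaining <- function(col, i) tot[col] - sum(cnt[seq_len(i - 1L), col])
  haz <- function(col, i) {
    r <- remaining(col, i)
    if (r <= 0) return(NaN)
    cnt[i, col] / r
  }
  out <- matrix(NA_real_, I - 1L, I - 1L,
                dimnames = list(paste0("h=", seq_len(I - 1L)),
                                paste0("i=", 2:I)))
  for (h in seq_len(I - 1L)) {
    for (i in (h + 1L):I) {
      out[h, i - 1L] <- haz(h, i) - haz(I + 1L, i)
    }
  }
  out
}
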