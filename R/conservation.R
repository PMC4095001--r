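## Conservation of contacts across an ensemble.
##
## For residue pair (k, l) seen in nc_kl of the N frames, the
## conservation rate is CR_kl = nc_kl / N: 1 when the contact is present
## in every frame, and pairs never in contact are omitted (their CR of 0
## is representable only implicitly in the consensus matrix).
##
## The overall conservation coefficient at threshold t is
##   C_t = nc_t / (sum_i nc_i / N),
## where nc_t counts distinct pairs with CR_kl >= t ("at least t")
## and the denominator is the mean number of contacts per frame.
## C_t is not a priori bounded by 1 under this normalisation (nc_t
## counts distinct pairs; the denominator is a per-frame mean) and is
## deliberately not clipped.

#' Per-pair conservation rates over an ensemble
#'
#' @param contact_sets ordered list of `contact_set`, one per frame.
#' @param n_frames number of analysed frames `N`; defaults to
#'   `length(contact_sets)`.
#' @return data frame of class `contact_records`, one row per residue
#'   pair observed in at least one frame, with columns `chain_a`,
#'   `resno_a`, `icode_a`, `resname_a`, `key_a`, the same for `b`,
#'   `nc` (frames containing the contact) and `cr` (`nc / n_frames`),
#'   sorted by chain and residue number of A then B.
#' @export
conservation_rates <- function(contact_sets, n_frames = length(contact_sets)) {
  if (length(contact_sets) == 0L) {
    mdc_stop("no contact sets supplied", "mdc_error_empty_input")
  }
  all_pairs <- do.call(rbind, lapply(contact_sets, function(cs) cs$pairs))
  if (is.null(all_pairs) || nrow(all_pairs) == 0L) {
    rec <- data.frame(chain_a = character(), resno_a = integer(),
                      icode_a = character(), resname_a = character(),
                      key_a = character(), chain_b = character(),
                      resno_b = integer(), icode_b = character(),
                      resname_b = character(), key_b = character(),
                      nc = integer(), cr = numeric())
    class(rec) <- c("contact_records", "data.frame")
    attr(rec, "n_frames") <- n_frames
    return(rec)
  }
  key <- paste(all_pairs$key_a, all_pairs$key_b, sep = "|")
  nc <- table(key)
  rec <- all_pairs[!duplicated(key),
                   c("chain_a", "resno_a", "icode_a", "resname_a", "key_a",
                     "chain_b", "resno_b", "icode_b", "resname_b", "key_b"),
                   drop = FALSE]
  rec$nc <- as.integer(nc[key[!duplicated(key)]])
  rec$cr <- rec$nc / n_frames
  rec <- rec[order(rec$chain_a, rec$resno_a, rec$icode_a,
                   rec$chain_b, rec$resno_b, rec$icode_b), , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("contact_records", "data.frame")
  attr(rec, "n_frames") <- n_frames
  rec
}

#' Overall conservation coefficients (C50/C70/C90)
#'
#' For each threshold t, counts the contacts conserved in at least a
#' fraction t of the frames (inclusive comparison) and normalises by the
#' mean number of contacts per frame.
#'
#' @param records output of [conservation_rates()].
#' @param nc_per_frame integer vector of per-frame contact counts
#'   (`n_contacts` of each frame's contact set).
#' @param thresholds conservation-fraction thresholds in (0, 1].
#' @return object of class `conservation_summary`: list with `n_frames`,
#'   `nc_per_frame`, `mean_nc`, `thresholds`, `nc_at_threshold` and
#'   `coefficients` (full precision; printing rounds to 2 decimals).
#' @export
conservation_coefficients <- function(records, nc_per_frame,
                                      thresholds = c(0.50, 0.70, 0.90)) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    mdc_stop("thresholds must lie in (0, 1]", "mdc_error_bad_threshold")
  }
  n <- attr(records, "n_frames") %||% length(nc_per_frame)
  if (length(nc_per_frame) != n) {
    mdc_stop("nc_per_frame length must equal the frame count",
             "mdc_error_bad_input")
  }
  total <- sum(nc_per_frame)
  if (total == 0L) {
    mdc_stop("no contacts in any frame: conservation coefficients undefined",
             "mdc_error_no_contacts")
  }
  mean_nc <- total / n
  nc_t <- vapply(thresholds, function(t) sum(records$cr >= t), integer(1))
  structure(
    list(n_frames = n, nc_per_frame = nc_per_frame, mean_nc = mean_nc,
         thresholds = thresholds, nc_at_threshold = nc_t,
         coefficients = nc_t / mean_nc),
    class = "conservation_summary")
}

#' Consensus matrix of conservation rates
#'
#' A partner-A (rows) by partner-B (columns) matrix holding CR_kl for
#' recorded pairs and 0 elsewhere; rows and columns follow the registry
#' order (chain, residue number, insertion code).
#'
#' @param records output of [conservation_rates()].
#' @param registry residue registry data frame (from an
#'   `md_trajectory`'s `registry` element) covering every pair member.
#' @return numeric matrix of class `consensus_matrix` with residue keys
#'   as dimnames and row/column annotation in attributes `row_info` /
#'   `col_info`.
#' @export
consensus_matrix <- function(records, registry) {
  rows <- registry[registry$partner == "A", , drop = FALSE]
  cols <- registry[registry$partner == "B", , drop = FALSE]
  rows <- rows[order(rows$chain, rows$resno, rows$icode), , drop = FALSE]
  cols <- cols[order(cols$chain, cols$resno, cols$icode), , drop = FALSE]
  m <- matrix(0, nrow(rows), nrow(cols),
              dimnames = list(rows$reskey, cols$reskey))
  if (nrow(records)) {
    if (!all(records$key_a %in% rows$reskey) ||
        !all(records$key_b %in% cols$reskey)) {
      mdc_stop("contact record involves a residue absent from the registry",
               "mdc_error_registry_mismatch")
    }
    m[cbind(match(records$key_a, rows$reskey),
            match(records$key_b, cols$reskey))] <- records$cr
  }
  structure(m, class = c("consensus_matrix", "matrix"),
            row_info = rows, col_info = cols)
}

#' Write the contact-record table as TSV
#'
#' Columns: chain_A, resnum_A, resname_A, chain_B, resnum_B, resname_B,
#' nc_kl, CR_kl (CR rounded to 2 decimals in the table; thresholds are
#' applied at full precision upstream).
#'
#' @param records output of [conservation_rates()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_records_tsv <- function(records, path) {
  tab <- data.frame(chain_A = records$chain_a, resnum_A = records$resno_a,
                    resname_A = records$resname_a,
                    chain_B = records$chain_b, resnum_B = records$resno_b,
                    resname_B = records$resname_b,
                    nc_kl = records$nc,
                    CR_kl = sprintf("%.2f", records$cr))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the conservation summary file
#'
#' One header section (N, mean contacts per frame) and one line per
#' threshold: t, nc_t, C_t.
#'
#' @param summary a `conservation_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("n_frames\t%d", summary$n_frames), con)
  writeLines(sprintf("mean_contacts_per_frame\t%.4f", summary$mean_nc), con)
  for (i in seq_along(summary$thresholds)) {
    writeLines(sprintf("C_%02.0f\t%d\t%.2f", 100 * summary$thresholds[i],
                       summary$nc_at_threshold[i], summary$coefficients[i]),
               con)
  }
  invisible(path)
}

#' Write a consensus matrix as labelled plain text
#'
#' Whitespace-delimited matrix with residue-key row and column labels,
#' suitable for external plotting.
#'
#' @param matrix a `consensus_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_matrix <- function(matrix, path) {
  m <- unclass(matrix)
  attr(m, "row_info") <- NULL
  attr(m, "col_info") <- NULL
  utils::write.table(format(round(m, 4), trim = TRUE), path, quote = FALSE,
                     sep = "\t", col.names = NA)
  invisible(path)
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf("conservation over %d frames (mean %.2f contacts/frame)\n",
              x$n_frames, x$mean_nc))
  for (i in seq_along(x$thresholds)) {
    cat(sprintf("  C_%02.0f = %.2f (%d contacts conserved in >= %.0f%% of frames)\n",
                100 * x$thresholds[i], x$coefficients[i],
                x$nc_at_threshold[i], 100 * x$thresholds[i]))
  }
  invisible(x)
}
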