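## Contact typing by residue polarity and residue-pair distance
## monitoring along a trajectory.

#' Load a residue-polarity table
#'
#' Two-column TSV (`resname`, `class` in {hydrophobic, hydrophilic})
#' covering the 20 standard residues. The shipped default is a
#' COCOMAPS-style dialect: hydrophobic = ALA, VAL, LEU, ILE, MET, PHE,
#' PRO, TRP, GLY; everything else (including CYS, TYR, HIS) is
#' hydrophilic. The file is editable so the dialect can be swapped.
#'
#' @param path TSV path; defaults to the shipped table.
#' @return named character vector mapping residue name to class.
#' @export
load_polarity <- function(path = system.file("extdata",
                                             "polarity_cocomaps.tsv",
                                             package = "mdcontacts")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(tab$class, tab$resname)
}

#' Classify contacts by the polarity of their residues
#'
#' Each contact record is assigned exactly one of three classes:
#' hydrophilic-hydrophilic, hydrophobic-hydrophobic, or mixed; the
#' class counts always sum to the number of records.
#'
#' @param records a `contact_records` data frame
#'   ([conservation_rates()]) or the `pairs` element of a
#'   [frame_contacts()] result.
#' @param polarity named class vector from [load_polarity()].
#' @param strict if `TRUE`, an unclassifiable residue name is an error;
#'   otherwise it resolves to `default_class` with a warning.
#' @param default_class class used for unknown residues when
#'   `strict = FALSE`.
#' @return list with `counts` (named integer vector over the three
#'   classes) and `class` (per-record class vector).
#' @export
classify_contact_types <- function(records, polarity = load_polarity(),
                                   strict = FALSE,
                                   default_class = "hydrophilic") {
  resolve <- function(resname) {
    cl <- unname(polarity[resname])
    if (anyNA(cl)) {
      bad <- unique(resname[is.na(cl)])
      if (strict) {
        mdc_stop(sprintf("unclassifiable residue name(s): %s",
                         paste(bad, collapse = ", ")),
                 "mdc_error_unknown_residue")
      }
      warning(sprintf("residue(s) %s assigned default polarity '%s'",
                      paste(bad, collapse = ", "), default_class))
      cl[is.na(cl)] <- default_class
    }
    cl
  }
  ca <- resolve(records$resname_a)
  cb <- resolve(records$resname_b)
  cls <- ifelse(ca == "hydrophilic" & cb == "hydrophilic",
                "hydrophilic-hydrophilic",
                ifelse(ca == "hydrophobic" & cb == "hydrophobic",
                       "hydrophobic-hydrophobic", "mixed"))
  lv <- c("hydrophilic-hydrophilic", "hydrophobic-hydrophobic", "mixed")
  list(counts = stats::setNames(as.integer(table(factor(cls, levels = lv))), lv),
       class = cls)
}

## resolve an atom selection within one frame; returns row indices
select_atoms <- function(frame, sel) {
  at <- frame$atoms
  keep <- at$is_heavy
  if (!is.null(sel$chain)) keep <- keep & at$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & at$resno %in% sel$resno
  if (!is.null(sel$atoms)) keep <- keep & at$name %in% sel$atoms
  which(keep)
}

#' Minimum-distance series between two atom selections
#'
#' Per frame, the minimum heavy-atom distance between two selections
#' (each a list with `chain`, `resno` and optional `atoms` atom-name
#' filter, e.g. `list(chain = "B", resno = 35, atoms = c("OD1",
#' "OD2"))`). The selections must target distinct partners. Frames in
#' which a selection matches no atom yield `NA`.
#'
#' @param traj an `md_trajectory`.
#' @param selection_a,selection_b selection lists as above.
#' @return a `distance_series` list: `per_frame_min` (length-N numeric,
#'   Angstrom) and the two selections.
#' @export
min_distance_series <- function(traj, selection_a, selection_b) {
  part <- function(sel) {
    unique(traj$registry$partner[traj$registry$chain %in% sel$chain])
  }
  pa <- part(selection_a)
  pb <- part(selection_b)
  if (length(pa) != 1L || length(pb) != 1L || pa == pb) {
    mdc_stop("selections must target distinct partners",
             "mdc_error_bad_selection")
  }
  mins <- vapply(traj$frames, function(fr) {
    ia <- select_atoms(fr, selection_a)
    ib <- select_atoms(fr, selection_b)
    if (length(ia) == 0L || length(ib) == 0L) return(NA_real_)
    xa <- as.matrix(fr$atoms[ia, c("x", "y", "z")])
    xb <- as.matrix(fr$atoms[ib, c("x", "y", "z")])
    sqrt(min(cross_dist2(xa, xb)))
  }, numeric(1))
  if (all(is.na(mins))) {
    mdc_stop("selections are empty in every frame", "mdc_error_bad_selection")
  }
  structure(list(selection_a = selection_a, selection_b = selection_b,
                 per_frame_min = mins),
            class = "distance_series")
}

#' Write a distance series as TSV
#'
#' Columns `frame`, optional `time_label`, `min_distance_A`.
#'
#' @param series a `distance_series`.
#' @param path output TSV path.
#' @param time_labels optional per-frame labels (e.g. ns).
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(series, path, time_labels = NULL) {
  n <- length(series$per_frame_min)
  tab <- data.frame(frame = seq_len(n) - 1L)
  if (!is.null(time_labels)) tab$time_label <- time_labels
  tab$min_distance_A <- round(series$per_frame_min, 3)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
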