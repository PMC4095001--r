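## Reading and writing multi-model PDB files into a trajectory of frames
## with a stable residue registry and A/B partner assignment.
##
## The reader is a vectorised fixed-column parser: it supports multi-model
## files whose MODELs differ in atom or residue roster (snapshots of a
## system where, e.g., altloc resolution differs per frame), resolves
## alternate locations by occupancy per frame, and drops waters and
## (optionally) HETATM records. bio3d's reader assumes one constant atom
## roster across MODELs, which this contract does not.

WATER_NAMES <- c("HOH", "WAT", "TIP3", "TIP4", "SOL", "DOD", "H2O")

#' Residue key strings
#'
#' A residue is identified within a frame by chain ID, author residue
#' number and insertion code. Keys are plain strings `"<chain>:<resno><icode>"`
#' so they can index vectors and matrix dimnames.
#'
#' @param chain,resno,icode character/integer/character vectors.
#' @return character vector of keys.
#' @keywords internal
residue_key <- function(chain, resno, icode) {
  paste0(chain, ":", resno, ifelse(icode == "" | is.na(icode), "", icode))
}

## Infer element from PDB atom name when the element column is blank.
## Protein convention: a leading digit or a name whose first letter
## (after digit stripping) is H/D marks a hydrogen/deuterium.
infer_element <- function(name) {
  nm <- gsub("[0-9' ]", "", name)
  first <- toupper(substr(nm, 1L, 1L))
  ifelse(first %in% c("H", "D"), "H", first)
}

parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(
      record = character(), serial = integer(), name = character(),
      alt = character(), resname = character(), chain = character(),
      resno = integer(), icode = character(), x = numeric(), y = numeric(),
      z = numeric(), occ = numeric(), element = character(),
      stringsAsFactors = FALSE
    ))
  }
  df <- data.frame(
    record = trimws(substr(lines, 1L, 6L)),
    serial = suppressWarnings(as.integer(substr(lines, 7L, 11L))),
    name = trimws(substr(lines, 13L, 16L)),
    alt = trimws(substr(lines, 17L, 17L)),
    resname = trimws(substr(lines, 18L, 20L)),
    chain = trimws(substr(lines, 22L, 22L)),
    resno = suppressWarnings(as.integer(substr(lines, 23L, 26L))),
    icode = trimws(substr(lines, 27L, 27L)),
    x = as.numeric(substr(lines, 31L, 38L)),
    y = as.numeric(substr(lines, 39L, 46L)),
    z = as.numeric(substr(lines, 47L, 54L)),
    occ = suppressWarnings(as.numeric(substr(lines, 55L, 60L))),
    element = trimws(substr(lines, 77L, 78L)),
    stringsAsFactors = FALSE
  )
  df$occ[is.na(df$occ)] <- 1
  blank <- df$element == ""
  df$element[blank] <- infer_element(df$name[blank])
  df$element <- toupper(df$element)
  df
}

## One frame from a parsed atom table: chain filtering, water/HETATM
## policy, altloc resolution, partner assignment.
build_frame <- function(atoms, index, chains_a, chains_b, include_het) {
  atoms <- atoms[!(atoms$resname %in% WATER_NAMES), , drop = FALSE]
  if (!include_het) {
    ## MSE is part of the polymer: keep it and map to MET
    mse <- atoms$record == "HETATM" & atoms$resname == "MSE"
    atoms$resname[mse] <- "MET"
    atoms$element[mse & atoms$element == "SE"] <- "S"
    atoms$name[mse & atoms$name == "SE"] <- "SD"
    atoms$record[mse] <- "ATOM"
    atoms <- atoms[atoms$record == "ATOM", , drop = FALSE]
  }
  atoms <- atoms[atoms$chain %in% c(chains_a, chains_b), , drop = FALSE]

  ## altloc: keep highest occupancy per (residue, atom name); ties keep
  ## the first-encountered conformer
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name)
    ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno,
                                     atoms$icode, atoms$name)), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }

  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  atoms$partner <- ifelse(atoms$chain %in% chains_a, "A", "B")
  atoms$reskey <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, index = index), class = "md_frame")
}

frame_registry <- function(frame) {
  a <- frame$atoms
  reg <- a[!duplicated(a$reskey),
           c("reskey", "chain", "resno", "icode", "resname", "partner")]
  rownames(reg) <- NULL
  reg
}

new_trajectory <- function(frames, chains_a, chains_b, source = NA_character_) {
  regs <- do.call(rbind, lapply(frames, frame_registry))
  regs <- regs[!duplicated(regs$reskey), , drop = FALSE]
  regs <- regs[order(regs$partner, regs$chain, regs$resno, regs$icode), ,
               drop = FALSE]
  rownames(regs) <- NULL
  for (p in c("A", "B")) {
    if (!any(regs$partner == p)) {
      mdc_stop(sprintf("partner %s has no residues in any frame", p),
               "mdc_error_empty_partner")
    }
  }
  structure(
    list(frames = frames, n_frames = length(frames), registry = regs,
         chains_a = chains_a, chains_b = chains_b, source = source),
    class = "md_trajectory"
  )
}

check_chain_args <- function(chains_a, chains_b) {
  if (length(intersect(chains_a, chains_b)) > 0L) {
    mdc_stop("chains_a and chains_b must be disjoint",
             "mdc_error_chain_overlap")
  }
}

split_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame (a file without `MODEL`
#' records is a single implicit frame). Only `ATOM` records of the listed
#' chains are retained; waters are always dropped; `HETATM` records are
#' dropped unless `include_het = TRUE` (selenomethionine is kept and
#' mapped to MET either way). Hydrogens are kept but flagged so that
#' contact detection and surface computations ignore them. Alternate
#' locations are resolved per frame to the highest-occupancy conformer
#' (ties: first encountered).
#'
#' @param path path to a PDB file.
#' @param chains_a,chains_b character vectors of chain IDs defining the
#'   two binding partners; must be disjoint and each must match at least
#'   one chain present in the file.
#' @param include_het keep non-water `HETATM` records?
#' @return an object of class `md_trajectory`: a list with `frames`
#'   (list of `md_frame`), `n_frames`, and a `registry` data frame of
#'   every residue seen in any frame with its partner assignment.
#' @seealso [read_snapshot_set()], [write_multimodel_pdb()]
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' generate_toy_complex(4, 4, slots = cbind(2, 2), path = pdb)
#' traj <- read_multimodel_pdb(pdb, "A", "B")
#' traj$n_frames
read_multimodel_pdb <- function(path, chains_a, chains_b,
                                include_het = FALSE) {
  if (!file.exists(path)) {
    mdc_stop(sprintf("file not found: %s", path), "mdc_error_missing_file")
  }
  check_chain_args(chains_a, chains_b)
  lines <- readLines(path, warn = FALSE)
  blocks <- split_models(lines)
  frames <- list()
  for (i in seq_along(blocks)) {
    atoms <- parse_pdb_atoms(blocks[[i]])
    if (nrow(atoms) == 0L) next
    frames[[length(frames) + 1L]] <-
      build_frame(atoms, index = length(frames), chains_a, chains_b,
                  include_het)
  }
  if (length(frames) == 0L) {
    mdc_stop(sprintf("no parseable models in %s", path),
             "mdc_error_no_models")
  }
  seen <- unique(unlist(lapply(frames, function(f) unique(f$atoms$chain))))
  if (!any(chains_a %in% seen)) {
    mdc_stop("no atoms found for chains_a", "mdc_error_no_matching_chains")
  }
  if (!any(chains_b %in% seen)) {
    mdc_stop("no atoms found for chains_b", "mdc_error_no_matching_chains")
  }
  new_trajectory(frames, chains_a, chains_b, source = path)
}

#' Read an ordered set of single-model PDB snapshots as a trajectory
#'
#' Frames are ordered as the input list; filtering rules are those of
#' [read_multimodel_pdb()]. The residue registry is the union of the
#' residues of all snapshots, so snapshots may differ in roster.
#'
#' @param paths character vector (ordered) of single-model PDB files.
#' @inheritParams read_multimodel_pdb
#' @return an `md_trajectory`.
#' @export
read_snapshot_set <- function(paths, chains_a, chains_b,
                              include_het = FALSE) {
  if (length(paths) == 0L) {
    mdc_stop("empty snapshot list", "mdc_error_missing_file")
  }
  check_chain_args(chains_a, chains_b)
  frames <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) {
      mdc_stop(sprintf("file not found: %s", paths[i]),
               "mdc_error_missing_file")
    }
    atoms <- parse_pdb_atoms(readLines(paths[i], warn = FALSE))
    if (nrow(atoms) == 0L) {
      mdc_stop(sprintf("no parseable atoms in %s", paths[i]),
               "mdc_error_no_models")
    }
    fr <- build_frame(atoms, index = i - 1L, chains_a, chains_b, include_het)
    if (!all(c("A", "B") %in% fr$atoms$partner)) {
      mdc_stop(sprintf("snapshot %s is missing one partner", paths[i]),
               "mdc_error_empty_partner")
    }
    frames[[i]] <- fr
  }
  new_trajectory(frames, chains_a, chains_b,
                 source = paste(paths, collapse = ";"))
}

#' Write a trajectory as a canonical multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame, coordinates to 3 decimals.
#' Extra header lines (e.g. provenance `REMARK`s) may be prepended.
#'
#' @param traj an `md_trajectory` (or a single `md_frame`).
#' @param path output file path.
#' @param remarks optional character vector of `REMARK` lines (written
#'   verbatim; supply the full line).
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path, remarks = character()) {
  frames <- if (inherits(traj, "md_frame")) list(traj) else traj$frames
  con <- file(path, "w")
  on.exit(close(con))
  if (length(remarks)) writeLines(remarks, con)
  for (i in seq_along(frames)) {
    a <- frames[[i]]$atoms
    writeLines(sprintf("MODEL     %4d", i), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (seq_len(nrow(a)) - 1L) %% 99999L + 1L,
      ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name),
      a$resname, a$chain, a$resno,
      ifelse(a$icode == "", " ", a$icode),
      a$x, a$y, a$z, a$occ, 0, a$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frame(s)\n", x$n_frames))
  cat(sprintf("  partner A (chains %s): %d residues\n",
              paste(x$chains_a, collapse = ","),
              sum(x$registry$partner == "A")))
  cat(sprintf("  partner B (chains %s): %d residues\n",
              paste(x$chains_b, collapse = ","),
              sum(x$registry$partner == "B")))
  invisible(x)
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("md_frame %d: %d atoms, %d residues\n", x$index,
              nrow(x$atoms), length(unique(x$atoms$reskey))))
  invisible(x)
}
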