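## Synthetic two-partner complexes with controlled contact persistence.
##
## Geometry: chain A residues sit on a line along x at a fixed spacing;
## chain B residues sit on a parallel line offset in z. A designated
## "slot" pair (i in A, j in B) is placed with its B residue directly
## above its A residue at 4.5 A (in contact under the 5 A criterion);
## every non-slot residue pair is >= 8 A apart. In a trajectory, each
## slot is independently in contact in a given frame with its
## persistence probability p, else displaced to the far line. Slots
## toggle independently: the generator emulates per-contact persistence
## statistics, not physically correlated dynamics.
##
## Residue names alternate ALA/SER so polarity classification is
## exercisable on synthetic interfaces.

CONTACT_Z <- 4.5
FAR_Z <- 20

toy_atoms <- function(n_res, chain, spacing, z, atoms_per_residue,
                      resname_cycle = c("ALA", "SER")) {
  stopifnot(atoms_per_residue %in% c(1L, 3L))
  names <- if (atoms_per_residue == 1L) "CB" else c("N", "CA", "C")
  ## extra atoms offset along y so inter-residue x gaps are preserved
  dy <- if (atoms_per_residue == 1L) 0 else c(-1.2, 0, 1.2)
  el <- substr(names, 1L, 1L)
  res <- rep(seq_len(n_res), each = atoms_per_residue)
  data.frame(
    record = "ATOM", serial = seq_along(res),
    name = rep(names, n_res), alt = "",
    resname = rep(resname_cycle, length.out = n_res)[res],
    chain = chain, resno = res, icode = "",
    x = (res - 1L) * spacing, y = rep(dy, n_res), z = z,
    occ = 1, element = rep(el, n_res),
    stringsAsFactors = FALSE)
}

toy_frame <- function(n_res_a, n_res_b, slots, spacing, atoms_per_residue,
                      in_contact, index = 0L) {
  a <- toy_atoms(n_res_a, "A", spacing, 0, atoms_per_residue)
  b <- toy_atoms(n_res_b, "B", spacing, FAR_Z, atoms_per_residue)
  if (length(in_contact) && any(in_contact)) {
    for (s in which(in_contact)) {
      ia <- slots[s, 1L]
      ib <- slots[s, 2L]
      sel <- b$resno == ib
      b$x[sel] <- (ia - 1L) * spacing + (b$x[sel] - (ib - 1L) * spacing)
      b$z[sel] <- CONTACT_Z
    }
  }
  at <- rbind(a, b)
  at$serial <- seq_len(nrow(at))
  build_frame(at, index = index, chains_a = "A", chains_b = "B",
              include_het = FALSE)
}

check_slots <- function(slots, n_res_a, n_res_b) {
  if (is.null(slots) || length(slots) == 0L) {
    return(matrix(integer(), 0L, 2L))
  }
  slots <- rbind(slots)
  if (ncol(slots) < 2L) mdc_stop("slots need two index columns",
                                 "mdc_error_bad_spec")
  if (any(slots[, 1L] < 1L | slots[, 1L] > n_res_a) ||
      any(slots[, 2L] < 1L | slots[, 2L] > n_res_b)) {
    mdc_stop("slot indices outside the residue ranges", "mdc_error_bad_spec")
  }
  if (anyDuplicated(slots[, 2L])) {
    mdc_stop("each partner-B residue may serve at most one slot",
             "mdc_error_bad_spec")
  }
  slots
}

#' Generate a single-frame toy complex
#'
#' Two chains of pseudo-residues (1 or 3 heavy atoms each) on parallel
#' lines. Slot pairs are placed at 4.5 A (in contact under the default
#' 5 A cutoff); all other inter-chain residue pairs are at least 8 A
#' apart.
#'
#' @param n_res_a,n_res_b residues per chain (>= 1).
#' @param slots two-column matrix (or vector of length 2) of slot pairs
#'   `(residue index in A, residue index in B)`; each B residue may
#'   serve one slot. `NULL` for no contacts.
#' @param spacing inter-residue spacing along the chain in Angstrom
#'   (> 0; keep >= 7 so non-slot pairs stay beyond 8 A).
#' @param atoms_per_residue 1 (a lone CB) or 3 (N, CA, C).
#' @param path optional output PDB path; written when non-`NULL`.
#' @return an `md_frame` (invisibly returns `path` written too, as the
#'   attribute `"path"`).
#' @export
generate_toy_complex <- function(n_res_a, n_res_b, slots = NULL,
                                 spacing = 8, atoms_per_residue = 1L,
                                 path = NULL) {
  if (spacing <= 0) mdc_stop("spacing must be positive",
                             "mdc_error_bad_spec")
  if (n_res_a < 1L || n_res_b < 1L) {
    mdc_stop("each chain needs at least one residue", "mdc_error_bad_spec")
  }
  slots <- check_slots(slots, n_res_a, n_res_b)
  fr <- toy_frame(n_res_a, n_res_b, slots, spacing, atoms_per_residue,
                  in_contact = rep(TRUE, nrow(slots)))
  if (!is.null(path)) {
    write_multimodel_pdb(fr, path)
    attr(fr, "path") <- path
  }
  fr
}

#' Persistence specification for a synthetic trajectory
#'
#' @param slots data frame or matrix with columns `(residue index in A,
#'   residue index in B, persistence probability p)`; probabilities in
#'   `[0, 1]`.
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @param n_res_a,n_res_b,spacing,atoms_per_residue geometry, as in
#'   [generate_toy_complex()].
#' @param schedule optional logical matrix (`n_frames` x number of
#'   slots) giving each slot's presence per frame explicitly; overrides
#'   the probabilistic draw (used for exactly scripted fixtures).
#' @return a `persistence_spec` list.
#' @export
persistence_spec <- function(slots, n_frames, seed = 1L,
                             n_res_a = NULL, n_res_b = NULL,
                             spacing = 8, atoms_per_residue = 1L,
                             schedule = NULL) {
  slots <- rbind(slots)
  if (ncol(slots) == 2L) slots <- cbind(slots, 1)
  if (any(slots[, 3L] < 0 | slots[, 3L] > 1)) {
    mdc_stop("persistence probabilities must lie in [0, 1]",
             "mdc_error_bad_spec")
  }
  if (n_frames < 1L) mdc_stop("n_frames must be >= 1", "mdc_error_bad_spec")
  n_res_a <- n_res_a %||% max(slots[, 1L], 2L)
  n_res_b <- n_res_b %||% max(slots[, 2L], 2L)
  check_slots(slots[, 1:2, drop = FALSE], n_res_a, n_res_b)
  if (!is.null(schedule)) {
    stopifnot(nrow(schedule) == n_frames, ncol(schedule) == nrow(slots))
  }
  structure(list(slots = slots, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), n_res_a = n_res_a,
                 n_res_b = n_res_b, spacing = spacing,
                 atoms_per_residue = as.integer(atoms_per_residue),
                 schedule = schedule),
            class = "persistence_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic multi-model trajectory
#'
#' Writes (or returns) a trajectory in which each slot contact is
#' present in each frame independently with its persistence
#' probability, drawn from a single seeded RNG stream; the output is
#' deterministic for a fixed spec. The seed is recorded in a `REMARK`
#' line of the written PDB.
#'
#' @param spec a [persistence_spec()].
#' @param path optional multi-model PDB output path.
#' @return an `md_trajectory`; when `path` is given the file is written
#'   and its path attached as attribute `"path"`.
#' @export
generate_trajectory <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "persistence_spec"))
  ns <- nrow(spec$slots)
  presence <- spec$schedule %||% with_seed(spec$seed, {
    matrix(stats::runif(spec$n_frames * ns) <
             rep(spec$slots[, 3L], each = spec$n_frames),
           spec$n_frames, ns)
  })
  frames <- lapply(seq_len(spec$n_frames), function(i) {
    toy_frame(spec$n_res_a, spec$n_res_b,
              spec$slots[, 1:2, drop = FALSE], spec$spacing,
              spec$atoms_per_residue,
              in_contact = if (ns) presence[i, ] else logical(),
              index = i - 1L)
  })
  traj <- new_trajectory(frames, "A", "B",
                         source = sprintf("synthetic(seed=%d)", spec$seed))
  if (!is.null(path)) {
    write_multimodel_pdb(traj, path,
                         remarks = sprintf("REMARK 250 SYNTHETIC TRAJECTORY SEED %d",
                                           spec$seed))
    attr(traj, "path") <- path
  }
  traj
}
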