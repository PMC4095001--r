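## Solvent-accessible surface area (SASA) and interface area.
##
## SASA is computed by Shrake-Rupley sphere sampling on heavy atoms:
## each atom's expanded sphere (vdW radius + probe) is covered with a
## deterministic golden-section spiral lattice of test points, and the
## accessible fraction is the fraction of points lying outside every
## neighbouring expanded sphere. Hydrogens contribute zero area and do
## not occlude. Because the lattice is deterministic, results are
## bit-reproducible for fixed parameters.
##
## The interface area of a complex is half the ASA buried on
## complexation: (ASA(A) + ASA(B) - ASA(AB)) / 2, isolated-partner
## terms computed by deleting the other partner's atoms from the same
## coordinates (no re-relaxation).

#' Load an atom-radius table
#'
#' Reads a radius dialect from a three-column TSV (`kind`, `key`,
#' `radius`): `atom` rules keyed by `"<resname> <atomname>"` (resname
#' `*` is a wildcard) take precedence over `element` fallbacks. The
#' shipped default is a Chothia-style table (tetrahedral C 1.87,
#' trigonal/aromatic C 1.76, N 1.65, O 1.40, S 1.85 Angstrom).
#'
#' @param path TSV path; defaults to the shipped Chothia-style table.
#' @return a `radius_set` list with `atom_rules` and `element_rules`
#'   named numeric vectors.
#' @export
load_radii <- function(path = system.file("extdata", "radii_chothia.tsv",
                                          package = "mdcontacts")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  structure(list(
    atom_rules = stats::setNames(tab$radius[tab$kind == "atom"],
                                 tab$key[tab$kind == "atom"]),
    element_rules = stats::setNames(tab$radius[tab$kind == "element"],
                                    tab$key[tab$kind == "element"])),
    class = "radius_set", source = path)
}

#' SASA parameters
#'
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points number of lattice points per atom (>= 100);
#'   960 gives < 1% error against the analytic isolated-sphere area.
#' @param radii a `radius_set` from [load_radii()].
#' @return a `sasa_params` list.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        radii = load_radii()) {
  if (probe_radius <= 0) {
    mdc_stop("probe_radius must be positive", "mdc_error_bad_params")
  }
  if (n_sphere_points < 100) {
    mdc_stop("n_sphere_points must be at least 100", "mdc_error_bad_params")
  }
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii = radii),
            class = "sasa_params")
}

## deterministic golden-section spiral lattice on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

## vdW radius per heavy atom; errors naming the first unresolvable atom
resolve_radii <- function(atoms, radii) {
  key <- paste(atoms$resname, atoms$name)
  r <- unname(radii$atom_rules[key])
  wild <- is.na(r)
  if (any(wild)) {
    r[wild] <- unname(radii$atom_rules[paste("*", atoms$name[wild])])
  }
  miss <- is.na(r)
  if (any(miss)) {
    r[miss] <- unname(radii$element_rules[atoms$element[miss]])
  }
  if (anyNA(r)) {
    bad <- which(is.na(r))[1L]
    mdc_stop(sprintf("no radius for atom %s of %s %s%d (element %s)",
                     atoms$name[bad], atoms$resname[bad], atoms$chain[bad],
                     atoms$resno[bad], atoms$element[bad]),
             "mdc_error_unknown_atom")
  }
  r
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley sampled area per atom, in the context of all heavy
#' atoms supplied. Hydrogens get area 0 and never occlude.
#'
#' @param atoms an `md_frame` or its atom data frame.
#' @param params a [sasa_params()] object.
#' @return numeric vector of per-atom areas in square Angstrom, in the
#'   input atom order.
#' @export
atom_sasa <- function(atoms, params = sasa_params()) {
  if (inherits(atoms, "md_frame")) atoms <- atoms$atoms
  heavy <- which(atoms$is_heavy)
  if (length(heavy) == 0L) {
    mdc_stop("no heavy atoms", "mdc_error_empty_partner")
  }
  xyz <- as.matrix(atoms[heavy, c("x", "y", "z")])
  rexp <- resolve_radii(atoms[heavy, , drop = FALSE], params$radii) +
    params$probe_radius
  n <- length(heavy)
  pts <- sphere_points(params$n_sphere_points)

  ## neighbour lists from one squared-distance pass (chunked)
  areas <- numeric(n)
  d2 <- cross_dist2(xyz, xyz)
  rsum2 <- outer(rexp, rexp, "+")^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < rsum2[i, ])
    nb <- nb[nb != i]
    p <- pts * rexp[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    if (length(nb)) {
      pd2 <- cross_dist2(p, xyz[nb, , drop = FALSE])
      acc <- rowSums(pd2 < matrix(rexp[nb]^2, nrow(pd2), length(nb),
                                  byrow = TRUE)) == 0L
    } else {
      acc <- rep(TRUE, nrow(p))
    }
    areas[i] <- 4 * pi * rexp[i]^2 * mean(acc)
  }
  out <- numeric(nrow(atoms))
  out[heavy] <- areas
  out
}

#' Interface area of one frame
#'
#' Half the solvent-accessible surface area buried upon complex
#' formation: `(ASA(A) + ASA(B) - ASA(AB)) / 2`, with the isolated
#' partners taken at the complex coordinates.
#'
#' @param frame an `md_frame` with both partners present.
#' @inheritParams atom_sasa
#' @return interface area in square Angstrom.
#' @export
interface_area <- function(frame, params = sasa_params()) {
  at <- frame$atoms
  if (!all(c("A", "B") %in% at$partner[at$is_heavy])) {
    mdc_stop("frame must contain heavy atoms of both partners",
             "mdc_error_empty_partner")
  }
  asa_a <- sum(atom_sasa(at[at$partner == "A", , drop = FALSE], params))
  asa_b <- sum(atom_sasa(at[at$partner == "B", , drop = FALSE], params))
  asa_ab <- sum(atom_sasa(at, params))
  (asa_a + asa_b - asa_ab) / 2
}

#' Interface area along a trajectory
#'
#' @param traj an `md_trajectory`.
#' @inheritParams atom_sasa
#' @param reference_area optional square-Angstrom area of a reference
#'   (e.g. X-ray) structure, carried through for plotting/reporting.
#' @return an `area_series` list: `per_frame_area`, `mean`, `sd`
#'   (sample sd; 0 with `sd_defined = FALSE` for a single frame) and
#'   `reference_area`.
#' @export
area_series <- function(traj, params = sasa_params(),
                        reference_area = NULL) {
  areas <- vapply(seq_along(traj$frames), function(i) {
    tryCatch(interface_area(traj$frames[[i]], params),
             mdc_error = function(e) {
               mdc_stop(sprintf("frame %d: %s", i - 1L, conditionMessage(e)),
                        class(e)[1L])
             })
  }, numeric(1))
  sd_defined <- length(areas) > 1L
  structure(list(per_frame_area = areas, mean = mean(areas),
                 sd = if (sd_defined) stats::sd(areas) else 0,
                 sd_defined = sd_defined,
                 reference_area = reference_area),
            class = "area_series")
}

#' Per-residue burial upon complex formation
#'
#' For every residue, its heavy-atom ASA in the isolated partner and in
#' the complex, and the burial percentage
#' `100 * (asa_free - asa_complex) / asa_free`. Residues with free ASA
#' below 0.1 square Angstrom are flagged (`pct_buried = NA`) rather
#' than divided.
#'
#' @inheritParams interface_area
#' @return data frame: `chain`, `resno`, `icode`, `resname`,
#'   `asa_free`, `asa_complex`, `pct_buried`.
#' @export
residue_burial <- function(frame, params = sasa_params()) {
  at <- frame$atoms
  if (!all(c("A", "B") %in% at$partner[at$is_heavy])) {
    mdc_stop("frame must contain heavy atoms of both partners",
             "mdc_error_empty_partner")
  }
  free <- numeric(nrow(at))
  for (p in c("A", "B")) {
    sel <- at$partner == p
    free[sel] <- atom_sasa(at[sel, , drop = FALSE], params)
  }
  complexed <- atom_sasa(at, params)
  keys <- unique(at$reskey)
  asa_free <- as.numeric(rowsum(free, at$reskey)[keys, ])
  asa_complex <- as.numeric(rowsum(complexed, at$reskey)[keys, ])
  info <- at[!duplicated(at$reskey), c("chain", "resno", "icode", "resname")]
  out <- data.frame(info, asa_free = asa_free, asa_complex = asa_complex,
                    pct_buried = ifelse(
                      asa_free < 0.1, NA_real_,
                      100 * (asa_free - asa_complex) / asa_free),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno, out$icode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a per-frame interface-area table as TSV
#'
#' Columns `frame`, `area_A2`, followed by comment lines giving the
#' ensemble mean, sample sd and (if supplied) the reference area.
#'
#' @param series an `area_series`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_area_tsv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("frame\tarea_A2", con)
  writeLines(sprintf("%d\t%.2f", seq_along(series$per_frame_area) - 1L,
                     series$per_frame_area), con)
  writeLines(sprintf("# mean\t%.2f", series$mean), con)
  writeLines(sprintf("# sd\t%.2f", series$sd), con)
  if (!is.null(series$reference_area)) {
    writeLines(sprintf("# reference\t%.2f", series$reference_area), con)
  }
  invisible(path)
}

#' Write a residue-burial report as TSV
#'
#' @param report output of [residue_burial()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_burial_tsv <- function(report, path) {
  tab <- data.frame(chain = report$chain, resnum = report$resno,
                    resname = report$resname,
                    asa_free = round(report$asa_free, 2),
                    asa_complex = round(report$asa_complex, 2),
                    pct_buried = round(report$pct_buried, 1))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.area_series <- function(x, ...) {
  cat(sprintf("interface area over %d frame(s): %.1f +/- %.1f A^2\n",
              length(x$per_frame_area), x$mean, x$sd))
  invisible(x)
}
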