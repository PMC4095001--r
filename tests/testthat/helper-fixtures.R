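# Shared fixtures and independent oracles.

# Brute-force contact oracle: exhaustive scan over every heavy-atom
# pair, independent of the package's chunked matrix search.
brute_contacts <- function(frame, cutoff = 5.0) {
  at <- frame$atoms
  ha <- at[at$is_heavy & at$partner == "A", , drop = FALSE]
  hb <- at[at$is_heavy & at$partner == "B", , drop = FALSE]
  found <- character()
  for (i in seq_len(nrow(ha))) {
    for (j in seq_len(nrow(hb))) {
      d <- sqrt((ha$x[i] - hb$x[j])^2 + (ha$y[i] - hb$y[j])^2 +
                  (ha$z[i] - hb$z[j])^2)
      if (d < cutoff) {
        found <- c(found, paste(ha$reskey[i], hb$reskey[j], sep = "|"))
      }
    }
  }
  sort(unique(found))
}

pair_keys <- function(contact_set) {
  sort(paste(contact_set$pairs$key_a, contact_set$pairs$key_b, sep = "|"))
}

# A frame of randomly placed residues (1-3 heavy atoms each) in a box,
# assembled through the public PDB writer/reader round trip.
random_frame <- function(n_res_a = 8, n_res_b = 8, box = 18,
                         max_atoms = 3L) {
  mk <- function(n, chain) {
    rows <- lapply(seq_len(n), function(r) {
      k <- sample.int(max_atoms, 1L)
      center <- runif(3, 0, box)
      data.frame(name = c("CA", "CB", "CG")[seq_len(k)],
                 resname = sample(c("ALA", "SER", "LEU", "ASP"), 1L),
                 chain = chain, resno = r,
                 x = center[1] + runif(k, -0.8, 0.8),
                 y = center[2] + runif(k, -0.8, 0.8),
                 z = center[3] + runif(k, -0.8, 0.8),
                 element = "C", stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  at <- rbind(mk(n_res_a, "A"), mk(n_res_b, "B"))
  path <- tempfile(fileext = ".pdb")
  writeLines(sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), paste0(" ", at$name), at$resname, at$chain,
    at$resno, at$x, at$y, at$z, 1, 0, at$element), path)
  traj <- read_multimodel_pdb(path, "A", "B")
  traj$frames[[1L]]
}

# Scripted-presence trajectory: slot s is present in frame i iff
# schedule[i, s]; bypasses the probabilistic draw.
scripted_trajectory <- function(slots, schedule, ...) {
  spec <- persistence_spec(slots, n_frames = nrow(schedule),
                           schedule = schedule, ...)
  generate_trajectory(spec)
}

# The 10-frame worked example: contact a present in 10 frames, b in 7,
# c in 3.
worked_toy <- function() {
  scripted_trajectory(
    slots = cbind(c(1, 2, 3), c(1, 2, 3)),
    schedule = cbind(rep(TRUE, 10),
                     rep(c(TRUE, FALSE), c(7, 3)),
                     rep(c(TRUE, FALSE), c(3, 7))))
}

# Apply a rigid-body transform to a frame (random rotation from QR of a
# Gaussian matrix, plus translation).
transform_frame <- function(frame, rot = NULL, shift = c(0, 0, 0)) {
  if (is.null(rot)) {
    qr_ <- qr(matrix(rnorm(9), 3))
    rot <- qr.Q(qr_)
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  }
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")]) %*% t(rot)
  frame$atoms$x <- xyz[, 1] + shift[1]
  frame$atoms$y <- xyz[, 2] + shift[2]
  frame$atoms$z <- xyz[, 3] + shift[3]
  frame
}

# Analytic SASA of each of two equal spheres of expanded radius R at
# centre distance d (0 < d < 2R): full sphere minus the buried cap.
two_sphere_each <- function(R, d) {
  4 * pi * R^2 - 2 * pi * R * (R - d / 2)
}

sasa_quick <- function(n = 960) sasa_params(n_sphere_points = n)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reference X-ray structures (author-supplied; not redistributable with
# the package sources). Tests that need them fail with an informative
# message when the files are absent.
reference_pdb <- function(code) {
  system.file("extdata", "reference", paste0(code, ".pdb"),
              package = "mdcontacts")
}

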