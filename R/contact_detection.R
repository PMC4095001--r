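## Intermolecular residue-residue contact detection.
##
## Two residues, one per partner, are in contact when at least one heavy
## atom of each lies at Euclidean distance strictly below the cutoff
## (default 5 A, the CAPRI convention). Distances are computed in double
## precision with no periodic-boundary imaging: snapshots are assumed
## whole/imaged upstream.

## cross squared-distance matrix between two coordinate sets (n x 3)
cross_dist2 <- function(xa, xb) {
  sa <- rowSums(xa^2)
  sb <- rowSums(xb^2)
  d2 <- outer(sa, sb, "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  d2
}

#' Intermolecular contacts of one frame
#'
#' Finds every residue pair (one residue per partner) with at least one
#' heavy-atom pair at distance strictly less than `cutoff`; a pair at
#' exactly the cutoff is not a contact. The result is identical to an
#' exhaustive scan over all heavy-atom pairs.
#'
#' @param frame an `md_frame`.
#' @param cutoff contact distance cutoff in Angstrom (> 0).
#' @return an object of class `contact_set`: list with `frame_index`,
#'   `pairs` (data frame with the two residue identities and the minimum
#'   heavy-atom distance of each contacting pair, sorted by chain and
#'   residue number), and `n_contacts`.
#' @export
#' @examples
#' fr <- generate_toy_complex(5, 5, slots = cbind(c(1, 3), c(1, 3)))
#' frame_contacts(fr)$n_contacts
frame_contacts <- function(frame, cutoff = 5.0) {
  if (!is.numeric(cutoff) || cutoff <= 0) {
    mdc_stop("cutoff must be a positive distance in Angstrom",
             "mdc_error_bad_cutoff")
  }
  at <- frame$atoms
  ha <- at[at$is_heavy & at$partner == "A", , drop = FALSE]
  hb <- at[at$is_heavy & at$partner == "B", , drop = FALSE]
  if (nrow(ha) == 0L || nrow(hb) == 0L) {
    mdc_stop("frame must contain heavy atoms of both partners",
             "mdc_error_empty_partner")
  }
  xa <- as.matrix(ha[, c("x", "y", "z")])
  xb <- as.matrix(hb[, c("x", "y", "z")])

  ## chunk over partner-A atoms to bound the distance-matrix size
  chunk <- max(1L, floor(4e7 / nrow(xb)))
  hits <- list()
  for (s in seq(1L, nrow(xa), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(xa))
    d2 <- cross_dist2(xa[s:e, , drop = FALSE], xb)
    idx <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(idx)) {
      hits[[length(hits) + 1L]] <- data.frame(
        ia = idx[, 1L] + s - 1L, ib = idx[, 2L],
        d = sqrt(d2[idx]))
    }
  }
  if (length(hits)) {
    h <- do.call(rbind, hits)
    key <- paste(ha$reskey[h$ia], hb$reskey[h$ib], sep = "|")
    mind <- tapply(h$d, key, min)
    first <- h[!duplicated(key), , drop = FALSE]
    ord_key <- key[!duplicated(key)]
    pairs <- data.frame(
      chain_a = ha$chain[first$ia], resno_a = ha$resno[first$ia],
      icode_a = ha$icode[first$ia], resname_a = ha$resname[first$ia],
      key_a = ha$reskey[first$ia],
      chain_b = hb$chain[first$ib], resno_b = hb$resno[first$ib],
      icode_b = hb$icode[first$ib], resname_b = hb$resname[first$ib],
      key_b = hb$reskey[first$ib],
      min_dist = as.numeric(mind[ord_key]),
      stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$chain_a, pairs$resno_a, pairs$icode_a,
                         pairs$chain_b, pairs$resno_b, pairs$icode_b), ,
                   drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(
      chain_a = character(), resno_a = integer(), icode_a = character(),
      resname_a = character(), key_a = character(),
      chain_b = character(), resno_b = integer(), icode_b = character(),
      resname_b = character(), key_b = character(),
      min_dist = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(frame_index = frame$index, pairs = pairs,
                 n_contacts = nrow(pairs)),
            class = "contact_set")
}

#' Contacts of every frame of a trajectory
#'
#' @param traj an `md_trajectory`.
#' @inheritParams frame_contacts
#' @return list of [frame_contacts()] results, one per frame, in frame
#'   order. Frame-level errors are re-raised with the frame index named.
#' @export
trajectory_contacts <- function(traj, cutoff = 5.0) {
  lapply(seq_along(traj$frames), function(i) {
    tryCatch(frame_contacts(traj$frames[[i]], cutoff),
             mdc_error = function(e) {
               mdc_stop(sprintf("frame %d: %s", i - 1L, conditionMessage(e)),
                        class(e)[1L])
             })
  })
}

#' Write per-frame contact lists as TSV
#'
#' Columns: frame, chain_A, resnum_A, resname_A, chain_B, resnum_B,
#' resname_B, min_distance_A.
#'
#' @param contact_sets list of `contact_set` (one per frame).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(contact_sets, path) {
  rows <- lapply(contact_sets, function(cs) {
    if (cs$n_contacts == 0L) return(NULL)
    data.frame(frame = cs$frame_index,
               chain_A = cs$pairs$chain_a, resnum_A = cs$pairs$resno_a,
               resname_A = cs$pairs$resname_a,
               chain_B = cs$pairs$chain_b, resnum_B = cs$pairs$resno_b,
               resname_B = cs$pairs$resname_b,
               min_distance_A = round(cs$pairs$min_dist, 3),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(frame = integer(), chain_A = character(),
                      resnum_A = integer(), resname_A = character(),
                      chain_B = character(), resnum_B = integer(),
                      resname_B = character(), min_distance_A = numeric())
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("contact_set (frame %d): %d intermolecular contacts\n",
              x$frame_index, x$n_contacts))
  invisible(x)
}
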