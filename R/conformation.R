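# signed dihedral (degrees, (-180, 180]) of four points given as rows
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi dihedral series of a conformer ensemble
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i) and psi(i) = N(i)-CA(i)-C(i)-N(i+1),
#' computed per frame per residue. phi is absent for the first residue and
#' psi for the last; residues with missing backbone atoms are flagged absent
#' (all-`NA` columns), not fatal.
#'
#' @param ensemble a `conformer_ensemble` whose atoms include `N`, `CA`,
#'   `C` per residue.
#' @return object of class `dihedral_series`: list with `residue_ids`,
#'   `resno`, and `phi`, `psi` matrices (frames x residues, degrees).
#' @export
backbone_dihedrals <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  at <- ensemble$atoms
  resnos <- sort(unique(at$resno))
  nres <- length(resnos)
  nf <- n_frames(ensemble)
  idx_of <- function(resno, name) {
    i <- which(at$resno == resno & at$name == name)
    if (length(i) == 1L) i else NA_integer_
  }
  N_i <- vapply(resnos, idx_of, integer(1L), name = "N")
  CA_i <- vapply(resnos, idx_of, integer(1L), name = "CA")
  C_i <- vapply(resnos, idx_of, integer(1L), name = "C")
  phi <- matrix(NA_real_, nf, nres)
  psi <- matrix(NA_real_, nf, nres)
  for (f in seq_len(nf)) {
    co <- ensemble$coords[, , f]
    for (r in seq_len(nres)) {
      if (r > 1L && !anyNA(c(C_i[r - 1L], N_i[r], CA_i[r], C_i[r])))
        phi[f, r] <- dihedral_angle(co[C_i[r - 1L], ], co[N_i[r], ],
                                    co[CA_i[r], ], co[C_i[r], ])
      if (r < nres && !anyNA(c(N_i[r], CA_i[r], C_i[r], N_i[r + 1L])))
        psi[f, r] <- dihedral_angle(co[N_i[r], ], co[CA_i[r], ],
                                    co[C_i[r], ], co[N_i[r + 1L], ])
    }
  }
  rid <- paste0(at$resname[match(resnos, at$resno)], resnos)
  structure(list(residue_ids = rid, resno = resnos, phi = phi, psi = psi),
            class = "dihedral_series")
}

#' Per-residue angular dispersion (PAD) of backbone dihedrals
#'
#' Quantifies backbone flexibility as a circular dispersion of the pooled
#' (phi, psi) angles across frames: with mean resultant length R of the
#' combined unit-vector representation, PAD = (180/pi) sqrt(-2 ln R),
#' capped at 180 degrees. A rigid residue (identical dihedrals in every
#' frame) scores 0; dispersion increases the score monotonically up to the
#' cap, which is attained in the uniform-on-the-circle limit. The estimator
#' is invariant to frame order and to duplicating all frames. The `metric`
#' argument accepts a replacement function(phi, psi) so that alternative
#' dispersion variants (phi-only, psi-only, or a different circular spread)
#' can be swapped in without touching callers.
#'
#' @param dihedrals a [backbone_dihedrals()] result.
#' @param metric dispersion function taking the phi and psi vectors (degrees,
#'   `NA` allowed) of one residue; default the pooled circular dispersion
#'   described above.
#' @return named numeric vector (one PAD value in \[0, 180\] per residue;
#'   `NA` where no angles are defined), class `pad_profile`.
#' @export
pad_profile <- function(dihedrals, metric = pad_circular) {
  stopifnot(inherits(dihedrals, "dihedral_series"))
  out <- vapply(seq_along(dihedrals$residue_ids), function(r)
    metric(dihedrals$phi[, r], dihedrals$psi[, r]), numeric(1L))
  names(out) <- dihedrals$residue_ids
  class(out) <- c("pad_profile", "numeric")
  out
}

#' @rdname pad_profile
#' @param phi,psi dihedral series of one residue, degrees.
#' @export
pad_circular <- function(phi, psi) {
  # combined resultant: each frame contributes the unit vectors of its phi
  # and psi; per-angle resultant lengths are combined in quadrature so an
  # ensemble of identical conformations scores exactly 0
  resultant2 <- function(a) {
    a <- a[is.finite(a)]
    if (length(a) < 2L) return(NA_real_)
    rad <- a * pi / 180
    mean(cos(rad))^2 + mean(sin(rad))^2
  }
  r2 <- c(resultant2(phi), resultant2(psi))
  r2 <- r2[!is.na(r2)]
  if (length(r2) == 0L) return(NA_real_)
  rbar <- min(1, sqrt(mean(r2)))
  # rigid ensembles must score exactly 0: absorb rounding around unity
  if (rbar >= 1 - 1e-12) return(0)
  if (rbar <= 0) return(180)
  min(180, (180 / pi) * sqrt(-2 * log(rbar)))
}

#' Assign alpha-helical residues from dihedral windows
#'
#' A residue is helical in a frame when both phi and psi fall inside the
#' alpha basin window and it belongs to a run of at least `min_run`
#' consecutive in-window residues (a lone in-window residue is not a helix).
#' This is a deliberately simple dihedral-window assignment, not a
#' hydrogen-bond-pattern method.
#'
#' @param dihedrals a [backbone_dihedrals()] result.
#' @param phi_window,psi_window numeric length-2 windows in degrees
#'   (defaults: phi in \[-100, -30\], psi in \[-67, -7\]).
#' @param min_run minimum run length of consecutive in-window residues
#'   (default 4).
#' @return logical matrix (frames x residues) of class `helix_mask`.
#' @export
assign_helix <- function(dihedrals, phi_window = c(-100, -30),
                         psi_window = c(-67, -7), min_run = 4L) {
  stopifnot(inherits(dihedrals, "dihedral_series"), min_run >= 1L)
  inwin <- !is.na(dihedrals$phi) & !is.na(dihedrals$psi) &
    dihedrals$phi >= phi_window[1L] & dihedrals$phi <= phi_window[2L] &
    dihedrals$psi >= psi_window[1L] & dihedrals$psi <= psi_window[2L]
  mask <- matrix(FALSE, nrow(inwin), ncol(inwin),
                 dimnames = list(NULL, dihedrals$residue_ids))
  for (f in seq_len(nrow(inwin))) {
    r <- rle(inwin[f, ])
    r$values <- r$values & r$lengths >= min_run
    mask[f, ] <- inverse.rle(r)
  }
  class(mask) <- c("helix_mask", class(mask))
  mask
}

#' Helical content of a trajectory
#'
#' Percentage of helical residue-frames: 100 x (helical flags) / (total
#' residue-frames), plus the same ratio per residue.
#'
#' @param mask a [assign_helix()] mask.
#' @return list with `overall` (percent) and `per_residue` (named percent
#'   vector).
#' @export
helical_content <- function(mask) {
  stopifnot(inherits(mask, "helix_mask"))
  m <- unclass(mask)
  list(overall = 100 * mean(m),
       per_residue = 100 * colMeans(m))
}
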