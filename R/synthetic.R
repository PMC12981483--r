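#' Ground-truth specification for synthetic titration records
#'
#' Describes a two-state protonation sampler whose deprotonated probability
#' follows the generalized Henderson-Hasselbalch curve at each pH, with
#' known (pKa, Hill n). Pure frames draw lambda uniformly from the matching
#' cutoff band (\[0.8, 1\] deprotonated, \[0, 0.2\] protonated) so the
#' classification cutoffs are genuinely exercised, and chi concentrated near
#' 0 or 1. A chosen fraction of frames is injected as mid-lambda mixing
#' states and another as mixed-tautomer (chi strictly inside (0.2, 0.8))
#' frames; both are what the state filter must discard, and the generator
#' keeps exact bookkeeping of them.
#'
#' @param pka_true true pKa of the simulated site.
#' @param hill_true true Hill coefficient (> 0).
#' @param ph_grid pH values at which records are generated.
#' @param n_samples_per_ph frames per pH.
#' @param mixed_chi_fraction fraction of frames injected with mixed chi.
#' @param mid_lambda_fraction fraction of frames injected with mid-band
#'   lambda.
#' @param seed integer seed; everything downstream is reproducible from it.
#' @param residue_id identifier written into the records.
#' @param markov_flip `NULL` for independent draws; otherwise a probability
#'   in (0, 1\]: each frame resamples its pure protonation state with this
#'   probability and keeps the previous state otherwise, giving an
#'   autocorrelated series with the same stationary law (stresses
#'   convergence diagnostics).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(pka_true, hill_true = 1, ph_grid = 3:7,
                           n_samples_per_ph = 1000L,
                           mixed_chi_fraction = 0, mid_lambda_fraction = 0,
                           seed = 1L, residue_id = "ASP1",
                           markov_flip = NULL) {
  stopifnot(is.numeric(pka_true), hill_true > 0, length(ph_grid) >= 1L,
            n_samples_per_ph >= 1L,
            mixed_chi_fraction >= 0, mixed_chi_fraction < 1,
            mid_lambda_fraction >= 0, mid_lambda_fraction < 1,
            mixed_chi_fraction + mid_lambda_fraction < 1)
  if (!is.null(markov_flip))
    stopifnot(markov_flip > 0, markov_flip <= 1)
  structure(list(pka_true = pka_true, hill_true = hill_true,
                 ph_grid = ph_grid,
                 n_samples_per_ph = as.integer(n_samples_per_ph),
                 mixed_chi_fraction = mixed_chi_fraction,
                 mid_lambda_fraction = mid_lambda_fraction,
                 seed = as.integer(seed), residue_id = residue_id,
                 markov_flip = markov_flip),
            class = "synthetic_spec")
}

#' Simulate lambda-dynamics titration records with known ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return named list (names = pH values as written by `format()`) of
#'   record data frames with columns `frame`, `residue_id`, `lambda`,
#'   `chi`. Each data frame carries a `bookkeeping` attribute counting the
#'   injected mid-lambda and mixed-chi frames (their sum is exactly the
#'   number the default cutoffs must discard); the list carries the `spec`.
#' @export
simulate_titration_records <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples_per_ph
  out <- lapply(spec$ph_grid, function(ph) {
    p_deprot <- hh_curve(ph, spec$pka_true, spec$hill_true)
    u <- stats::runif(n)
    category <- ifelse(u < spec$mid_lambda_fraction, "mid",
                       ifelse(u < spec$mid_lambda_fraction +
                                spec$mixed_chi_fraction, "mixed", "pure"))
    if (is.null(spec$markov_flip)) {
      deprot <- stats::runif(n) < p_deprot
    } else {
      fresh <- stats::runif(n) < p_deprot
      resample <- stats::runif(n) < spec$markov_flip
      resample[1L] <- TRUE
      deprot <- logical(n)
      for (k in seq_len(n))
        deprot[k] <- if (resample[k]) fresh[k] else deprot[k - 1L]
    }
    lambda <- ifelse(category == "mid", stats::runif(n, 0.2, 0.8),
                     ifelse(deprot, stats::runif(n, 0.8, 1.0),
                            stats::runif(n, 0.0, 0.2)))
    chi <- ifelse(category == "mixed", stats::runif(n, 0.2, 0.8),
                  ifelse(stats::runif(n) < 0.5,
                         stats::runif(n, 0.0, 0.15),
                         stats::runif(n, 0.85, 1.0)))
    rec <- data.frame(frame = seq_len(n) - 1L,
                      residue_id = spec$residue_id,
                      lambda = lambda, chi = chi)
    attr(rec, "bookkeeping") <- list(
      n_mid_lambda = sum(category == "mid"),
      n_mixed_chi = sum(category == "mixed"),
      n_discarded_expected = sum(category != "pure"),
      n_pure = sum(category == "pure"))
    rec
  })
  names(out) <- format(spec$ph_grid, trim = TRUE)
  attr(out, "spec") <- spec
  out
}

#' An engineered donor/acceptor contact for toy ensembles
#'
#' @param donor_res,acceptor_res residue numbers carrying the contact's
#'   donor hydroxyl and acceptor oxygen.
#' @param n_waters bridging waters, 0 (direct H-bond) to 3.
#' @param target_occupancy percent of frames, in (0, 100\], in which the
#'   contact geometry satisfies the H-bond criteria.
#' @return list describing the contact.
#' @export
engineered_contact <- function(donor_res, acceptor_res, n_waters = 0L,
                               target_occupancy = 100) {
  if (!n_waters %in% 0:3)
    stop("unrealizable contact: water chains longer than 3 cannot form a ",
         "bridge under the detection rules")
  if (!(target_occupancy > 0 && target_occupancy <= 100))
    stop("target_occupancy must lie in (0, 100]")
  list(donor_res = as.integer(donor_res),
       acceptor_res = as.integer(acceptor_res),
       n_waters = as.integer(n_waters),
       target_occupancy = target_occupancy)
}

#' Specification of a toy peptide/water conformer ensemble
#'
#' @param sequence one-letter amino-acid string.
#' @param helix_span integer range of residues built with ideal alpha-helix
#'   dihedrals (default: the whole chain); residues outside the span are
#'   built extended.
#' @param dihedral_noise_sigma Gaussian noise (degrees) added independently
#'   to every phi/psi in every frame.
#' @param engineered_contacts list of [engineered_contact()]s.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return object of class `toy_structure_spec`.
#' @export
toy_structure_spec <- function(sequence, helix_span = NULL,
                               dihedral_noise_sigma = 0,
                               engineered_contacts = list(),
                               n_frames = 10L, seed = 1L) {
  nres <- nchar(sequence)
  stopifnot(nres >= 2L, n_frames >= 1L, dihedral_noise_sigma >= 0)
  if (is.null(helix_span)) helix_span <- c(1L, nres)
  stopifnot(helix_span[1L] >= 1L, helix_span[2L] <= nres)
  for (ct in engineered_contacts)
    if (ct$donor_res > nres || ct$acceptor_res > nres ||
        ct$donor_res < 1L || ct$acceptor_res < 1L)
      stop("engineered contact references residues outside the sequence")
  structure(list(sequence = toupper(sequence), helix_span = helix_span,
                 dihedral_noise_sigma = dihedral_noise_sigma,
                 engineered_contacts = engineered_contacts,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "toy_structure_spec")
}

# place point d with |cd| = bond, angle(b,c,d) = theta, dihedral(a,b,c,d) = chi
nerf_place <- function(a, b, c, bond, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  d2 <- c(bond * cos(pi - th),
          bond * sin(pi - th) * cos(ch),
          bond * sin(pi - th) * sin(ch))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- c((b - a)[2] * bc[3] - (b - a)[3] * bc[2],
         (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
         (b - a)[1] * bc[2] - (b - a)[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# backbone N/CA/C/O/H coordinates for one frame given per-residue (phi, psi)
build_backbone <- function(phi, psi) {
  nres <- length(phi)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231; b_NH <- 0.98
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7
  atoms <- list(); coords <- list()
  N <- c(0, 0, 0)
  CA <- c(b_NCA, 0, 0)
  C <- CA + b_CAC * c(cos(pi - a_NCAC * pi / 180),
                      sin(pi - a_NCAC * pi / 180), 0)
  prevC <- NULL
  for (r in seq_len(nres)) {
    if (r > 1L) {
      N <- nerf_place(prev$N, prev$CA, prev$C, b_CN, a_CACN, psi[r - 1L])
      CA <- nerf_place(prev$CA, prev$C, N, b_NCA, a_CNCA, 180)
      C <- nerf_place(prev$C, N, CA, b_CAC, a_NCAC, phi[r])
      H <- nerf_place(prev$CA, prev$C, N, b_NH, 119, 0)
      atoms[[length(atoms) + 1L]] <- c("H", r); coords[[length(coords) + 1L]] <- H
    }
    atoms[[length(atoms) + 1L]] <- c("N", r); coords[[length(coords) + 1L]] <- N
    atoms[[length(atoms) + 1L]] <- c("CA", r); coords[[length(coords) + 1L]] <- CA
    atoms[[length(atoms) + 1L]] <- c("C", r); coords[[length(coords) + 1L]] <- C
    O <- if (r < nres) {
      nerf_place(N, CA, C, b_CO, 120.8, psi[r] - 180)
    } else {
      nerf_place(N, CA, C, b_CO, 120.8, 0)
    }
    atoms[[length(atoms) + 1L]] <- c("O", r); coords[[length(coords) + 1L]] <- O
    prev <- list(N = N, CA = CA, C = C)
  }
  nm <- do.call(rbind, atoms)
  list(name = nm[, 1L], resno = as.integer(nm[, 2L]),
       xyz = do.call(rbind, coords))
}

#' Build a toy peptide/water conformer ensemble with known ground truth
#'
#' The backbone is grown from ideal alpha-helix dihedrals (phi = -57,
#' psi = -47 inside the helix span; extended outside) with independent
#' Gaussian noise per frame, using ideal bond geometry. Each engineered
#' contact adds a donor hydroxyl on the donor residue, an acceptor oxygen
#' on the acceptor residue and, when requested, a chain of 1-3 bridging
#' waters, all placed collinearly at 2.9 A spacing (ideal H-bond geometry)
#' in the frames where the contact is "on" — decided by independent
#' Bernoulli draws at the target occupancy — and stretched beyond the
#' distance cutoff in "off" frames. Contact assemblies are laid out well
#' away from the backbone and from each other so no unintended H-bond can
#' form. The realized per-contact occupancies are recorded in the
#' `engineered` attribute.
#'
#' @param spec a [toy_structure_spec()].
#' @return a `conformer_ensemble` (writable with [write_pdb_models()]) with
#'   attribute `engineered`: data frame of contacts and realized
#'   occupancies.
#' @export
build_toy_ensemble <- function(spec) {
  stopifnot(inherits(spec, "toy_structure_spec"))
  set.seed(spec$seed)
  aa3 <- bio3d::aa123(strsplit(spec$sequence, "")[[1L]])
  nres <- length(aa3)
  nf <- spec$n_frames
  in_helix <- seq_len(nres) >= spec$helix_span[1L] &
    seq_len(nres) <= spec$helix_span[2L]
  phi0 <- ifelse(in_helix, -57, -135)
  psi0 <- ifelse(in_helix, -47, 135)

  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    phi <- phi0 + stats::rnorm(nres, 0, spec$dihedral_noise_sigma)
    psi <- psi0 + stats::rnorm(nres, 0, spec$dihedral_noise_sigma)
    frames[[f]] <- build_backbone(phi, psi)
  }
  bb_extent <- range(vapply(frames, function(fr) max(fr$xyz[, 2L]),
                            numeric(1L)))
  y0 <- bb_extent[2L] + 12  # clearance so contact assemblies never touch it

  topo_name <- frames[[1L]]$name
  topo_resno <- frames[[1L]]$resno
  topo_resname <- aa3[topo_resno]

  contacts <- spec$engineered_contacts
  on_mat <- NULL
  extra_name <- character(0); extra_resno <- integer(0)
  extra_resname <- character(0)
  if (length(contacts) > 0L) {
    on_mat <- matrix(FALSE, nf, length(contacts))
    for (k in seq_along(contacts)) {
      ct <- contacts[[k]]
      on_mat[, k] <- stats::runif(nf) < ct$target_occupancy / 100
      # donor hydroxyl, bridging waters, acceptor oxygen (chain along +y)
      extra_name <- c(extra_name, "OX", "HX")
      extra_resno <- c(extra_resno, ct$donor_res, ct$donor_res)
      extra_resname <- c(extra_resname, aa3[ct$donor_res], aa3[ct$donor_res])
      if (ct$n_waters > 0L)
        for (w in seq_len(ct$n_waters)) {
          extra_name <- c(extra_name, "OW", "HW1", "HW2")
          wat_res <- 1000L + 10L * k + w
          extra_resno <- c(extra_resno, rep(wat_res, 3L))
          extra_resname <- c(extra_resname, rep("HOH", 3L))
        }
      extra_name <- c(extra_name, "OY")
      extra_resno <- c(extra_resno, ct$acceptor_res)
      extra_resname <- c(extra_resname, aa3[ct$acceptor_res])
    }
  }

  all_names <- c(topo_name, extra_name)
  all_resno <- c(topo_resno, extra_resno)
  all_resname <- c(topo_resname, extra_resname)
  natoms <- length(all_names)
  coords <- array(NA_real_, dim = c(natoms, 3L, nf))
  nbb <- length(topo_name)
  for (f in seq_len(nf)) {
    coords[seq_len(nbb), , f] <- frames[[f]]$xyz
    if (length(contacts) > 0L) {
      at <- nbb
      for (k in seq_along(contacts)) {
        ct <- contacts[[k]]
        # 2.9 A spacing in "on" frames keeps every link inside the criteria;
        # 4.5 A spacing in "off" frames breaks every link
        spacing <- if (on_mat[f, k]) 2.9 else 4.5
        x <- 9 * (k - 1L)
        yy <- y0
        coords[at + 1L, , f] <- c(x, yy, 0)              # OX donor oxygen
        coords[at + 2L, , f] <- c(x, yy + 0.98, 0)       # HX toward chain
        at <- at + 2L
        yy <- yy + spacing
        if (ct$n_waters > 0L)
          for (w in seq_len(ct$n_waters)) {
            coords[at + 1L, , f] <- c(x, yy, 0)          # OW
            coords[at + 2L, , f] <- c(x, yy + 0.98, 0)   # HW1 toward next
            coords[at + 3L, , f] <- c(x + 0.95, yy - 0.3, 0)  # HW2 aside
            at <- at + 3L
            yy <- yy + spacing
          }
        coords[at + 1L, , f] <- c(x, yy, 0)              # OY acceptor
        at <- at + 1L
      }
    }
  }
  atoms <- data.frame(serial = seq_len(natoms), name = all_names,
                      resname = all_resname, resno = all_resno,
                      chain = "A", stringsAsFactors = FALSE)
  ens <- structure(list(atoms = atoms, coords = coords),
                   class = "conformer_ensemble")
  if (length(contacts) > 0L) {
    attr(ens, "engineered") <- data.frame(
      donor = paste0(aa3[vapply(contacts, `[[`, 1L, "donor_res")],
                     vapply(contacts, `[[`, 1L, "donor_res")),
      acceptor = paste0(aa3[vapply(contacts, `[[`, 1L, "acceptor_res")],
                        vapply(contacts, `[[`, 1L, "acceptor_res")),
      n_waters = vapply(contacts, `[[`, 1L, "n_waters"),
      target_occupancy = vapply(contacts, function(x) x$target_occupancy,
                                numeric(1L)),
      realized_occupancy = 100 * colMeans(on_mat))
  }
  ens
}
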