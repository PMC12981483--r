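# Fixture builders shared across the suite. Everything is generated in code
# under explicit seeds; no binary fixtures.

# random titration record series for one residue (not via the package's
# generator, so count_states can be checked against an independent tally)
random_records <- function(n, seed, with_chi = TRUE) {
  set.seed(seed)
  data.frame(frame = seq_len(n) - 1L,
             residue_id = "ASP1",
             lambda = runif(n),
             chi = if (with_chi) runif(n) else NA_real_)
}

# independent one-record-at-a-time state tally (oracle for count_states)
naive_tally <- function(records, cutoffs) {
  nd <- np <- nx <- 0L
  for (k in seq_len(nrow(records))) {
    lam <- records$lambda[k]; chi <- records$chi[k]
    pure <- is.na(chi) || chi < cutoffs$chi_pure_low ||
      chi > cutoffs$chi_pure_high
    if (lam >= cutoffs$deprot_lambda_min && pure) nd <- nd + 1L
    else if (lam <= cutoffs$prot_lambda_max && pure) np <- np + 1L
    else nx <- nx + 1L
  }
  c(n_deprot = nd, n_prot = np, n_discarded = nx)
}

# a hand-placed frame: donor residue (O-H), optional water chain, acceptor
# residue, all collinear along +x at the given spacing
linear_contact_frame <- function(spacing = 2.9, n_waters = 0L,
                                 h_offset = 0.98, bend_deg = 0) {
  rows <- list()
  add <- function(name, resname, resno, x, y = 0, z = 0)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, resname = resname,
                                             resno = resno, x = x, y = y,
                                             z = z)
  add("OG", "SER", 1L, 0)
  # donor hydrogen, optionally bent off the D...A axis
  th <- bend_deg * pi / 180
  add("HG", "SER", 1L, h_offset * cos(th), h_offset * sin(th))
  x <- spacing
  if (n_waters > 0L)
    for (w in seq_len(n_waters)) {
      add("OW", "HOH", 100L + w, x)
      add("HW1", "HOH", 100L + w, x + h_offset)
      add("HW2", "HOH", 100L + w, x - 0.3, 0.95)
      x <- x + spacing
    }
  add("OD1", "ASP", 2L, x)
  do.call(rbind, rows)
}

# random small group/water system for the brute-force graph oracle:
# each "protein group" is one residue with a hydroxyl (donor+acceptor);
# waters have O + 2 H. Coordinates uniform in a box.
random_hbond_system <- function(n_groups, n_waters, seed, box = 12) {
  set.seed(seed)
  rows <- list()
  for (g in seq_len(n_groups)) {
    p <- runif(3, 0, box)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    rows[[length(rows) + 1L]] <- data.frame(
      name = c("OG", "HG"), resname = "SER", resno = g,
      x = c(p[1], p[1] + 0.98 * u[1]), y = c(p[2], p[2] + 0.98 * u[2]),
      z = c(p[3], p[3] + 0.98 * u[3]))
  }
  for (w in seq_len(n_waters)) {
    p <- runif(3, 0, box)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    rows[[length(rows) + 1L]] <- data.frame(
      name = c("OW", "HW1", "HW2"), resname = "HOH", resno = 100L + w,
      x = p[1] + 0.98 * c(0, u[1], 0.3 * u[1] + 0.95 * v[1]),
      y = p[2] + 0.98 * c(0, u[2], 0.3 * u[2] + 0.95 * v[2]),
      z = p[3] + 0.98 * c(0, u[3], 0.3 * u[3] + 0.95 * v[3]))
  }
  do.call(rbind, rows)
}

# naive pairwise H-bond check used by the oracle: explicit loops, no shared
# code with the package implementation
oracle_hbond_pair <- function(frame, d_idx, a_idx, criteria) {
  if (frame$resno[d_idx] == frame$resno[a_idx]) return(FALSE)
  dvec <- c(frame$x[d_idx], frame$y[d_idx], frame$z[d_idx])
  avec <- c(frame$x[a_idx], frame$y[a_idx], frame$z[a_idx])
  if (sqrt(sum((dvec - avec)^2)) > criteria$max_da_distance) return(FALSE)
  hs <- which(frame$resno == frame$resno[d_idx] &
              substr(frame$name, 1, 1) == "H")
  for (h in hs) {
    hvec <- c(frame$x[h], frame$y[h], frame$z[h])
    if (sqrt(sum((hvec - dvec)^2)) > 1.25) next
    v1 <- dvec - hvec; v2 <- avec - hvec
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    if (180 - ang <= criteria$max_angle_deviation) return(TRUE)
  }
  FALSE
}

# exhaustive enumeration of direct pairs and <= 3-water simple paths
oracle_graph <- function(frame, criteria) {
  heavy <- which(substr(frame$name, 1, 1) %in% c("O", "N"))
  is_wat <- frame$resname[heavy] == "HOH"
  # undirected link matrix over heavy polar atoms (either side donating)
  n <- length(heavy)
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (oracle_hbond_pair(frame, heavy[i], heavy[j], criteria))
      link[i, j] <- link[j, i] <- TRUE
  }
  gid <- paste0(frame$resname[heavy], frame$resno[heavy])
  groups <- unique(gid[!is_wat])
  waters <- unique(gid[is_wat])
  inc <- matrix(FALSE, length(groups), length(waters),
                dimnames = list(groups, waters))
  W <- matrix(FALSE, length(waters), length(waters),
              dimnames = list(waters, waters))
  direct <- matrix(FALSE, length(groups), length(groups),
                   dimnames = list(groups, groups))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!link[i, j]) next
    if (!is_wat[i] && !is_wat[j] && gid[i] != gid[j])
      direct[gid[i], gid[j]] <- direct[gid[j], gid[i]] <- TRUE
    if (!is_wat[i] && is_wat[j]) inc[gid[i], gid[j]] <- TRUE
    if (is_wat[i] && !is_wat[j]) inc[gid[j], gid[i]] <- TRUE
    if (is_wat[i] && is_wat[j] && gid[i] != gid[j])
      W[gid[i], gid[j]] <- TRUE
  }
  bridges <- list()
  ng <- length(groups); nw <- length(waters)
  if (ng >= 2L && nw >= 1L)
    for (a in seq_len(ng - 1L)) for (b in (a + 1L):ng) {
      best <- NA_integer_
      for (w1 in seq_len(nw)) {
        if (!inc[a, w1]) next
        if (inc[b, w1]) best <- min(best, 1L, na.rm = TRUE)
        if (criteria$max_bridge_waters >= 2L)
          for (w2 in seq_len(nw)) {
            if (w2 == w1 || !W[w1, w2]) next
            if (inc[b, w2]) best <- min(best, 2L, na.rm = TRUE)
            if (criteria$max_bridge_waters >= 3L)
              for (w3 in seq_len(nw)) {
                if (w3 %in% c(w1, w2) || !W[w2, w3]) next
                if (inc[b, w3]) best <- min(best, 3L, na.rm = TRUE)
              }
          }
      }
      if (!is.na(best))
        bridges[[length(bridges) + 1L]] <-
          data.frame(node_a = min(groups[a], groups[b]),
                     node_b = max(groups[a], groups[b]), n_waters = best)
    }
  dpairs <- which(direct & upper.tri(direct), arr.ind = TRUE)
  direct_df <- if (nrow(dpairs) > 0L) {
    data.frame(node_a = pmin(groups[dpairs[, 1L]], groups[dpairs[, 2L]]),
               node_b = pmax(groups[dpairs[, 1L]], groups[dpairs[, 2L]]))
  } else data.frame(node_a = character(), node_b = character())
  direct_df <- unique(direct_df)
  list(direct = direct_df[order(direct_df$node_a, direct_df$node_b), ,
                          drop = FALSE],
       bridges = if (length(bridges) > 0L) do.call(rbind, bridges)
                 else data.frame(node_a = character(), node_b = character(),
                                 n_waters = integer()))
}

# frame table -> single-frame conformer ensemble
frame_to_ensemble <- function(frame) {
  conformer_ensemble(frame[, c("name", "resname", "resno")],
                     as.matrix(frame[, c("x", "y", "z")]))
}

# canonical "a|b" pair keys for set comparisons
pair_keys <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(pmin(df$node_a, df$node_b), pmax(df$node_a, df$node_b),
             sep = "|"))
}

# random 3D rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3)))
}
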