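#' Geometric hydrogen-bond criteria
#'
#' An H-bond is accepted when the donor and acceptor heteroatoms are within
#' `max_da_distance` and the donor-H...acceptor arrangement deviates from
#' linearity by at most `max_angle_deviation` (a perfectly linear bond scores
#' 0 degrees). Water bridges may pass through at most `max_bridge_waters`
#' mutually H-bonded waters.
#'
#' @param max_da_distance donor-acceptor heteroatom distance cutoff in
#'   Angstrom (default 3.5).
#' @param max_angle_deviation angular deviation cutoff in degrees; the
#'   conventional choices are 20 (strict) and 60 (permissive).
#' @param max_bridge_waters maximum number of bridging waters, 1-3
#'   (default 3).
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, max_angle_deviation = 60,
                           max_bridge_waters = 3L) {
  stopifnot(is.numeric(max_da_distance), max_da_distance > 0,
            is.numeric(max_angle_deviation),
            max_angle_deviation > 0, max_angle_deviation <= 90,
            max_bridge_waters %in% 1:3)
  structure(list(max_da_distance = max_da_distance,
                 max_angle_deviation = max_angle_deviation,
                 max_bridge_waters = as.integer(max_bridge_waters)),
            class = "hbond_criteria")
}

#' Donor/acceptor chemistry rules
#'
#' Defines how donors, hydrogens and acceptors are resolved from atom
#' records: nitrogen and oxygen heavy atoms act as acceptors; those with a
#' hydrogen within `h_bond_length` in the same residue act as donors through
#' each such hydrogen. Water residues are recognised by name. Backbone
#' membership (for graph-set selection) is decided by atom name. Protonation
#' states couple to H-bonding through the titratable hydrogens: a
#' deprotonated carboxylate loses its hydroxyl hydrogen and becomes
#' acceptor-only, while the protonated form gains the donor hydroxyl;
#' neutral histidine donates on a single ring nitrogen.
#'
#' @param polar_elements elements eligible as donors/acceptors.
#' @param water_resnames residue names identifying water molecules.
#' @param h_bond_length covalent X-H bond cutoff in Angstrom used to attach
#'   hydrogens to their heavy atom.
#' @param backbone_atoms atom names treated as backbone for graph-set
#'   selection.
#' @param titratable_hydrogens named list, residue type to the hydrogen
#'   names removed when that residue is deprotonated.
#' @return object of class `donor_acceptor_table`.
#' @export
donor_acceptor_table <- function(polar_elements = c("N", "O"),
                                 water_resnames = c("HOH", "WAT", "TIP3",
                                                    "TIP", "SOL", "SPC"),
                                 h_bond_length = 1.25,
                                 backbone_atoms = c("N", "CA", "C", "O", "OXT",
                                                    "OT1", "OT2", "H", "HN",
                                                    "HA", "H1", "H2", "H3",
                                                    "HT1", "HT2", "HT3"),
                                 titratable_hydrogens = list(
                                   ASP = c("HD1", "HD2"),
                                   GLU = c("HE1", "HE2"),
                                   HIS = "HD1")) {
  structure(list(polar_elements = polar_elements,
                 water_resnames = water_resnames,
                 h_bond_length = h_bond_length,
                 backbone_atoms = backbone_atoms,
                 titratable_hydrogens = titratable_hydrogens),
            class = "donor_acceptor_table")
}

# element symbol from a PDB atom name ("OD1" -> "O", "HD21" -> "H")
atom_element <- function(name) {
  toupper(substr(gsub("^[0-9']+", "", name), 1L, 1L))
}

#' Remove titratable hydrogens of deprotonated residues
#'
#' Applies per-residue protonation states to a coordinate frame before
#' H-bond detection: residues declared deprotonated lose the titratable
#' hydrogens listed in the donor/acceptor table, so their carboxylates (or
#' histidine ring nitrogen) stop donating. Residues not named keep their
#' modeled hydrogens.
#'
#' @param frame atom data frame (columns `name`, `resname`, `resno`, `x`,
#'   `y`, `z`).
#' @param states named character vector: names are node ids such as
#'   `"ASP6"`, values `"protonated"` or `"deprotonated"`.
#' @param table a [donor_acceptor_table()].
#' @return the frame with the affected hydrogens removed.
#' @export
apply_protonation_states <- function(frame, states,
                                     table = donor_acceptor_table()) {
  if (length(states) == 0L) return(frame)
  stopifnot(all(states %in% c("protonated", "deprotonated")))
  node <- paste0(frame$resname, frame$resno)
  drop <- rep(FALSE, nrow(frame))
  for (rid in names(states)[states == "deprotonated"]) {
    type <- residue_type(rid)
    hs <- table$titratable_hydrogens[[type]]
    if (is.null(hs)) next
    drop <- drop | (node == rid & frame$name %in% hs)
  }
  frame[!drop, , drop = FALSE]
}

#' Detect hydrogen bonds in a single coordinate frame
#'
#' Applies the geometric criteria to every donor-hydrogen/acceptor
#' combination: the pair is reported when the heavy-atom distance is within
#' the cutoff and at least one donor hydrogen deviates from D-H...A
#' linearity by no more than the angular cutoff. Donors lacking a resolvable
#' hydrogen simply cannot donate (a message is emitted once per frame when
#' requested); intra-residue pairs are excluded.
#'
#' @param frame atom data frame with columns `name`, `resname`, `resno`,
#'   `x`, `y`, `z` (one frame of an ensemble; see [ensemble_frame()]).
#' @param table a [donor_acceptor_table()].
#' @param criteria an [hbond_criteria()].
#' @param warn_orphans emit a message listing polar heavy atoms with no
#'   attached hydrogen (they are skipped as donors, kept as acceptors).
#' @return data frame with one row per detected bond: donor/acceptor atom
#'   names and residues, the hydrogen used, distance, angular deviation,
#'   water/backbone flags.
#' @export
detect_hbonds_frame <- function(frame, table = donor_acceptor_table(),
                                criteria = hbond_criteria(),
                                warn_orphans = FALSE) {
  stopifnot(inherits(table, "donor_acceptor_table"),
            inherits(criteria, "hbond_criteria"))
  el <- atom_element(frame$name)
  heavy <- which(el %in% table$polar_elements)
  hyd <- which(el == "H")
  empty <- data.frame(donor_idx = integer(), h_idx = integer(),
                      acceptor_idx = integer(), donor_res = character(),
                      acceptor_res = character(), distance = numeric(),
                      deviation = numeric(), donor_water = logical(),
                      acceptor_water = logical(), donor_sidechain = logical(),
                      acceptor_sidechain = logical())
  if (length(heavy) < 2L) return(empty)
  xyz <- as.matrix(frame[, c("x", "y", "z")])

  # attach hydrogens to their heavy atom (same residue, within bond length)
  h_owner <- integer(0)
  h_atom <- integer(0)
  for (h in hyd) {
    same <- heavy[frame$resno[heavy] == frame$resno[h] &
                  frame$resname[heavy] == frame$resname[h]]
    if (length(same) == 0L) next
    d2 <- colSums((t(xyz[same, , drop = FALSE]) - xyz[h, ])^2)
    j <- same[which.min(d2)]
    if (min(d2) <= table$h_bond_length^2) {
      h_owner <- c(h_owner, j)
      h_atom <- c(h_atom, h)
    }
  }
  donors <- unique(h_owner)
  if (warn_orphans) {
    orphan <- setdiff(heavy[el[heavy] == "N"], donors)
    if (length(orphan) > 0L)
      message("polar atoms with no resolvable hydrogen (acceptor-only): ",
              paste(unique(paste0(frame$resname[orphan], frame$resno[orphan],
                                  "/", frame$name[orphan])), collapse = ", "))
  }
  if (length(donors) == 0L) return(empty)

  dmat <- as.matrix(stats::dist(xyz[heavy, , drop = FALSE]))
  res_of <- frame$resno[heavy]
  rows <- vector("list", 64L); nr <- 0L
  for (di in seq_along(heavy)) {
    D <- heavy[di]
    if (!D %in% donors) next
    hs <- h_atom[h_owner == D]
    near <- which(dmat[di, ] <= criteria$max_da_distance &
                  res_of != frame$resno[D])
    for (ai in near) {
      A <- heavy[ai]
      devs <- vapply(hs, function(h) {
        v1 <- xyz[D, ] - xyz[h, ]
        v2 <- xyz[A, ] - xyz[h, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      }, numeric(1L))
      best <- which.min(devs)
      if (devs[best] <= criteria$max_angle_deviation) {
        nr <- nr + 1L
        if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nr]] <- data.frame(
          donor_idx = D, h_idx = hs[best], acceptor_idx = A,
          donor_res = paste0(frame$resname[D], frame$resno[D]),
          acceptor_res = paste0(frame$resname[A], frame$resno[A]),
          distance = dmat[di, ai], deviation = devs[best],
          donor_water = frame$resname[D] %in% table$water_resnames,
          acceptor_water = frame$resname[A] %in% table$water_resnames,
          donor_sidechain = !(frame$name[D] %in% table$backbone_atoms) &&
            !frame$resname[D] %in% table$water_resnames,
          acceptor_sidechain = !(frame$name[A] %in% table$backbone_atoms) &&
            !frame$resname[A] %in% table$water_resnames)
      }
    }
  }
  if (nr == 0L) return(empty)
  do.call(rbind, rows[seq_len(nr)])
}

#' Detect water-mediated bridges between protein groups in one frame
#'
#' A bridge between two protein groups exists when a chain
#' group - w1 \[- w2 \[- w3\]\] - group can be walked in which every
#' consecutive link satisfies the H-bond criteria (in either donation
#' direction). The minimal water count per group pair is recorded; water
#' identities and path multiplicity are ignored — a pair either bridges in a
#' frame or it does not.
#'
#' @inheritParams detect_hbonds_frame
#' @param hbonds optional precomputed result of [detect_hbonds_frame()] for
#'   this frame (recomputed if `NULL`).
#' @return data frame with columns `node_a`, `node_b`, `n_waters` (minimal
#'   bridge length), `sidechain` (`TRUE` when some admissible bridge
#'   attaches through side-chain atoms at both ends; that bridge may be
#'   longer than `n_waters`).
#' @export
detect_water_bridges <- function(frame, table = donor_acceptor_table(),
                                 criteria = hbond_criteria(), hbonds = NULL) {
  if (is.null(hbonds)) hbonds <- detect_hbonds_frame(frame, table, criteria)
  empty <- data.frame(node_a = character(), node_b = character(),
                      n_waters = integer(), sidechain = logical())
  if (nrow(hbonds) == 0L) return(empty)

  gw <- hbonds[xor(hbonds$donor_water, hbonds$acceptor_water), , drop = FALSE]
  ww <- hbonds[hbonds$donor_water & hbonds$acceptor_water, , drop = FALSE]
  if (nrow(gw) == 0L) return(empty)

  wat_id <- ifelse(gw$donor_water, gw$donor_res, gw$acceptor_res)
  grp_id <- ifelse(gw$donor_water, gw$acceptor_res, gw$donor_res)
  grp_sc <- ifelse(gw$donor_water, gw$acceptor_sidechain, gw$donor_sidechain)
  waters <- unique(c(wat_id, ww$donor_res, ww$acceptor_res))
  groups <- unique(grp_id)
  nw <- length(waters); ng <- length(groups)
  if (nw == 0L || ng < 2L) return(empty)

  # group-water incidence (any attachment / side-chain attachment)
  inc_any <- matrix(FALSE, ng, nw, dimnames = list(groups, waters))
  inc_sc <- inc_any
  for (k in seq_len(nrow(gw))) {
    inc_any[grp_id[k], wat_id[k]] <- TRUE
    if (grp_sc[k]) inc_sc[grp_id[k], wat_id[k]] <- TRUE
  }
  # water-water adjacency (undirected, zero diagonal)
  W <- matrix(FALSE, nw, nw, dimnames = list(waters, waters))
  if (nrow(ww) > 0L)
    for (k in seq_len(nrow(ww))) {
      W[ww$donor_res[k], ww$acceptor_res[k]] <- TRUE
      W[ww$acceptor_res[k], ww$donor_res[k]] <- TRUE
    }

  # reach[[d]]: group x water, waters reachable through d-1 water-water hops
  reach <- vector("list", criteria$max_bridge_waters)
  reach_sc <- vector("list", criteria$max_bridge_waters)
  reach[[1L]] <- inc_any
  reach_sc[[1L]] <- inc_sc
  if (criteria$max_bridge_waters >= 2L)
    for (d in 2:criteria$max_bridge_waters) {
      reach[[d]] <- (reach[[d - 1L]] %*% W) > 0
      reach_sc[[d]] <- (reach_sc[[d - 1L]] %*% W) > 0
    }

  out <- list(); nr <- 0L
  for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
    found <- NA_integer_; found_sc <- FALSE
    for (d in seq_len(criteria$max_bridge_waters)) {
      # path g_i - w1 ... w_d - g_j: w_d attached to g_j, reachable from g_i
      if (is.na(found) && any(reach[[d]][i, ] & inc_any[j, ]))
        found <- d
      if (!found_sc && any(reach_sc[[d]][i, ] & inc_sc[j, ]))
        found_sc <- TRUE
    }
    if (!is.na(found)) {
      nr <- nr + 1L
      out[[nr]] <- data.frame(node_a = groups[i], node_b = groups[j],
                              n_waters = found, sidechain = found_sc)
    }
  }
  if (nr == 0L) return(empty)
  do.call(rbind, out)
}

# one frame's edge records at residue-group granularity
frame_edges <- function(frame, table, criteria) {
  hb <- detect_hbonds_frame(frame, table, criteria)
  direct <- hb[!hb$donor_water & !hb$acceptor_water, , drop = FALSE]
  d_edges <- if (nrow(direct) > 0L) {
    a <- pmin(direct$donor_res, direct$acceptor_res)
    b <- pmax(direct$donor_res, direct$acceptor_res)
    sc <- direct$donor_sidechain & direct$acceptor_sidechain
    agg <- stats::aggregate(sc, by = list(node_a = a, node_b = b), FUN = any)
    data.frame(node_a = agg$node_a, node_b = agg$node_b,
               kind = "direct", n_waters = 0L, sidechain = agg$x)
  } else NULL
  br <- detect_water_bridges(frame, table, criteria, hbonds = hb)
  b_edges <- if (nrow(br) > 0L) {
    a <- pmin(br$node_a, br$node_b); b <- pmax(br$node_a, br$node_b)
    data.frame(node_a = a, node_b = b, kind = "water_bridged",
               n_waters = br$n_waters, sidechain = br$sidechain)
  } else NULL
  rbind(d_edges, b_edges)
}

#' Extract one frame of a conformer ensemble as an atom table
#'
#' @param ensemble a `conformer_ensemble`.
#' @param f frame index.
#' @return atom data frame with coordinates for that frame.
#' @export
ensemble_frame <- function(ensemble, f) {
  stopifnot(inherits(ensemble, "conformer_ensemble"),
            f >= 1L, f <= n_frames(ensemble))
  a <- ensemble$atoms
  a$x <- ensemble$coords[, 1L, f]
  a$y <- ensemble$coords[, 2L, f]
  a$z <- ensemble$coords[, 3L, f]
  a
}

#' Accumulate per-frame H-bond detections into occupancies
#'
#' Occupancy of an interaction is the percentage of analysed frames in which
#' it satisfies the criteria. Direct and water-bridged occupancies are
#' tracked separately; the per-frame presence records are retained so that
#' [build_graph()] can re-aggregate them under each graph set's admission
#' rule.
#'
#' @param ensemble a `conformer_ensemble`, or a list of per-frame edge
#'   tables as produced internally.
#' @param table a [donor_acceptor_table()].
#' @param criteria an [hbond_criteria()].
#' @param frames optional integer vector of frame indices to analyse
#'   (default: all frames).
#' @param states optional protonation states passed to
#'   [apply_protonation_states()] before detection.
#' @return object of class `hbond_occupancy`: `edges` (summary data frame
#'   with `node_a`, `node_b`, `kind`, `min_waters_observed`, `occupancy`),
#'   `per_frame` (list of per-frame edge tables), `n_frames`.
#' @export
accumulate_occupancy <- function(ensemble, table = donor_acceptor_table(),
                                 criteria = hbond_criteria(), frames = NULL,
                                 states = NULL) {
  if (inherits(ensemble, "conformer_ensemble")) {
    if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
    per_frame <- lapply(frames, function(f) {
      fr <- ensemble_frame(ensemble, f)
      if (!is.null(states)) fr <- apply_protonation_states(fr, states, table)
      frame_edges(fr, table, criteria)
    })
  } else {
    stopifnot(is.list(ensemble))
    per_frame <- ensemble
  }
  N <- length(per_frame)
  if (N == 0L) stop("no frames to analyse")
  all_edges <- do.call(rbind, per_frame[!vapply(per_frame, is.null, TRUE)])
  if (is.null(all_edges) || nrow(all_edges) == 0L) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        kind = character(), min_waters_observed = integer(),
                        occupancy = numeric())
  } else {
    key <- paste(all_edges$node_a, all_edges$node_b, all_edges$kind, sep = "|")
    frame_of <- rep(seq_along(per_frame),
                    vapply(per_frame, function(x) if (is.null(x)) 0L else nrow(x),
                           integer(1L)))
    n_present <- tapply(frame_of, key, function(f) length(unique(f)))
    min_w <- tapply(all_edges$n_waters, key, min)
    parts <- do.call(rbind, strsplit(names(n_present), "|", fixed = TRUE))
    edges <- data.frame(node_a = parts[, 1L], node_b = parts[, 2L],
                        kind = parts[, 3L],
                        min_waters_observed = as.integer(min_w),
                        occupancy = 100 * as.numeric(n_present) / N)
    edges <- edges[order(edges$node_a, edges$node_b, edges$kind), ]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, per_frame = per_frame, n_frames = N),
            class = "hbond_occupancy")
}

#' @export
print.hbond_occupancy <- function(x, ...) {
  cat(sprintf("H-bond occupancies over %d frames: %d interaction(s)\n",
              x$n_frames, nrow(x$edges)))
  if (nrow(x$edges) > 0L) print(utils::head(x$edges, 20L))
  invisible(x)
}

# canonical (set, angle) -> occupancy threshold mapping
table1_thresholds <- list(
  backbone_sidechain_water = c(`20` = 10, `60` = 50),
  sidechain_water = c(`20` = 10, `60` = 25),
  sidechain_direct = c(`20` = 10, `60` = 15))

#' Specification of one H-bond graph set
#'
#' Three graph sets are computed: (1) direct H-bonds of backbone and side
#' chains plus water-mediated bridges; (2) side-chain to side-chain
#' interactions, direct or water-mediated; (3) direct side-chain to
#' side-chain H-bonds only. Each (set, angle criterion) pair carries a
#' canonical minimum-occupancy threshold — 10% throughout at 20 degrees, and
#' 50/25/15% for sets 1/2/3 at 60 degrees. A threshold inconsistent with
#' that mapping is rejected unless `allow_override = TRUE`.
#'
#' @param graph_set one of `"backbone_sidechain_water"`,
#'   `"sidechain_water"`, `"sidechain_direct"` (or 1, 2, 3).
#' @param angle_criterion 20 or 60 (degrees of angular deviation).
#' @param occupancy_threshold minimum occupancy percent; default the
#'   canonical value for the (set, angle) pair.
#' @param allow_override permit a non-canonical threshold.
#' @return object of class `graph_spec`.
#' @export
graph_spec <- function(graph_set = c("backbone_sidechain_water",
                                     "sidechain_water", "sidechain_direct"),
                       angle_criterion = 60, occupancy_threshold = NULL,
                       allow_override = FALSE) {
  if (is.numeric(graph_set))
    graph_set <- names(table1_thresholds)[graph_set]
  graph_set <- match.arg(graph_set)
  if (!angle_criterion %in% c(20, 60))
    stop("angle_criterion must be 20 or 60 degrees")
  canonical <- table1_thresholds[[graph_set]][[as.character(angle_criterion)]]
  if (is.null(occupancy_threshold)) occupancy_threshold <- canonical
  if (!allow_override && occupancy_threshold != canonical)
    stop(sprintf(paste0("occupancy threshold %s%% is inconsistent with the ",
                        "canonical mapping for %s at %d degrees (%s%%); ",
                        "set allow_override = TRUE to force"),
                 format(occupancy_threshold), graph_set,
                 angle_criterion, format(canonical)))
  if (occupancy_threshold < 0 || occupancy_threshold > 100)
    stop("occupancy threshold must be a percentage in [0,100]")
  structure(list(graph_set = graph_set, angle_criterion = angle_criterion,
                 occupancy_threshold = occupancy_threshold),
            class = "graph_spec")
}

# does an edge record qualify for a graph set?
edge_qualifies <- function(edges, graph_set) {
  switch(graph_set,
         backbone_sidechain_water = rep(TRUE, nrow(edges)),
         sidechain_water = edges$sidechain,
         sidechain_direct = edges$sidechain & edges$kind == "direct",
         stop("unknown graph set"))
}

#' Build an H-bond network graph from accumulated occupancies
#'
#' For the chosen graph set, a residue pair is present in a frame when at
#' least one qualifying interaction (per the set's admission rule) exists in
#' that frame; the pair's occupancy is the percentage of such frames, and
#' the edge is kept when that occupancy meets the set's threshold. Edges are
#' undirected and do not distinguish donation from acceptance.
#'
#' @param occupancies an [accumulate_occupancy()] result (its per-frame
#'   records must stem from detection at the same angular criterion as
#'   `spec$angle_criterion`).
#' @param spec a [graph_spec()].
#' @return list of class `hbond_graph` with `edges` (data frame `node_a`,
#'   `node_b`, `kind`, `min_waters_observed`, `occupancy`), `graph` (an
#'   [igraph][igraph::graph_from_data_frame] object) and `spec`.
#' @export
build_graph <- function(occupancies, spec) {
  stopifnot(inherits(occupancies, "hbond_occupancy"),
            inherits(spec, "graph_spec"))
  N <- occupancies$n_frames
  qualified <- lapply(occupancies$per_frame, function(ed) {
    if (is.null(ed) || nrow(ed) == 0L) return(NULL)
    ed <- ed[edge_qualifies(ed, spec$graph_set), , drop = FALSE]
    if (nrow(ed) == 0L) NULL else ed
  })
  # a pair is present in a frame if any qualifying interaction exists there
  keys_by_frame <- lapply(qualified, function(ed) {
    if (is.null(ed)) character(0)
    else unique(paste(ed$node_a, ed$node_b, sep = "|"))
  })
  tab <- table(unlist(keys_by_frame))
  if (length(tab) == 0L) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        kind = character(), min_waters_observed = integer(),
                        occupancy = numeric())
  } else {
    allq <- do.call(rbind, qualified)
    qkey <- paste(allq$node_a, allq$node_b, sep = "|")
    kind <- vapply(names(tab), function(k)
      if (any(allq$kind[qkey == k] == "direct")) "direct" else "water_bridged",
      character(1L))
    minw <- vapply(names(tab), function(k) min(allq$n_waters[qkey == k]),
                   numeric(1L))
    parts <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
    edges <- data.frame(node_a = parts[, 1L], node_b = parts[, 2L],
                        kind = unname(kind),
                        min_waters_observed = as.integer(minw),
                        occupancy = 100 * as.numeric(tab) / N)
    edges <- edges[edges$occupancy >= spec$occupancy_threshold, , drop = FALSE]
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  g <- if (nrow(edges) > 0L) {
    igraph::graph_from_data_frame(edges, directed = FALSE)
  } else igraph::make_empty_graph(directed = FALSE)
  structure(list(edges = edges, graph = g, spec = spec),
            class = "hbond_graph")
}

#' @export
print.hbond_graph <- function(x, ...) {
  cat(sprintf("H-bond graph [%s, %d deg, >= %s%%]: %d node(s), %d edge(s)\n",
              x$spec$graph_set, x$spec$angle_criterion,
              format(x$spec$occupancy_threshold),
              igraph::vcount(x$graph), nrow(x$edges)))
  if (nrow(x$edges) > 0L) print(x$edges)
  invisible(x)
}

#' Export an H-bond graph
#'
#' Writes the edge list as CSV (`node_a`, `node_b`, `kind`, `occupancy`) and
#' optionally the graph in GraphML for network-visualisation tools. Output
#' is deterministic: identical graphs yield byte-identical files.
#'
#' @param graph an `hbond_graph` from [build_graph()].
#' @param csv_path path for the CSV edge list (`NULL` to skip).
#' @param graphml_path path for a GraphML export (`NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_hbond_graph <- function(graph, csv_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(graph, "hbond_graph"))
  if (!is.null(csv_path)) {
    ed <- graph$edges[, c("node_a", "node_b", "kind", "occupancy")]
    utils::write.csv(ed, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(graphml_path))
    igraph::write_graph(graph$graph, graphml_path, format = "graphml")
  invisible(c(csv = csv_path, graphml = graphml_path))
}
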