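test_that("constructed geometries obey the distance and angle criteria", {
  tab <- donor_acceptor_table()
  # collinear D-H...A at 2.9 A: detected under both angle criteria
  fr <- linear_contact_frame(spacing = 2.9)
  for (ang in c(20, 60)) {
    hb <- detect_hbonds_frame(fr, tab, hbond_criteria(3.5, ang))
    expect_true(any(hb$donor_res == "SER1" & hb$acceptor_res == "ASP2"))
  }
  # 3.6 A with perfect angle: outside the heteroatom cutoff
  hb <- detect_hbonds_frame(linear_contact_frame(spacing = 3.6), tab,
                            hbond_criteria(3.5, 60))
  expect_equal(nrow(hb), 0L)
  # 40-degree deviation at 3.0 A: passes 60, fails 20
  bent <- linear_contact_frame(spacing = 3.0, bend_deg = 40)
  expect_true(nrow(detect_hbonds_frame(bent, tab, hbond_criteria(3.5, 60))) > 0)
  expect_equal(nrow(detect_hbonds_frame(bent, tab, hbond_criteria(3.5, 20))), 0L)
})

test_that("water bridges require 1-3 linked waters between the endpoint groups", {
  tab <- donor_acceptor_table()
  crit <- hbond_criteria(3.5, 60, 3L)
  for (nw in 1:3) {
    fr <- linear_contact_frame(spacing = 2.9, n_waters = nw)
    br <- detect_water_bridges(fr, tab, crit)
    expect_equal(nrow(br), 1L)
    expect_equal(br$n_waters, nw)
    expect_setequal(c(br$node_a, br$node_b), c("SER1", "ASP2"))
  }
  # 4-water chain: no admissible bridge
  fr4 <- linear_contact_frame(spacing = 2.9, n_waters = 4L)
  expect_equal(nrow(detect_water_bridges(fr4, tab, crit)), 0L)
  # direct contact is not a bridge
  fr0 <- linear_contact_frame(spacing = 2.9)
  expect_equal(nrow(detect_water_bridges(fr0, tab, crit)), 0L)
  # tighter max_bridge_waters prunes longer chains
  fr2 <- linear_contact_frame(spacing = 2.9, n_waters = 2L)
  expect_equal(nrow(detect_water_bridges(fr2, tab, hbond_criteria(3.5, 60, 1L))),
               0L)
})

test_that("occupancy is the percentage of frames in which an interaction is present", {
  on <- linear_contact_frame(spacing = 2.9)
  off <- linear_contact_frame(spacing = 4.6)
  ens <- models_to_ensemble(lapply(1:4, function(f) {
    fr <- if (f <= 2) on else off
    structure(list(model_index = f,
                   atoms = cbind(serial = seq_len(nrow(fr)), fr,
                                 chain = "A")[, c("serial", "name", "resname",
                                                  "resno", "chain", "x", "y",
                                                  "z")],
                   source = "synthetic"), class = "structure_model")
  }))
  occ <- accumulate_occupancy(ens)
  edge <- occ$edges[occ$edges$kind == "direct", ]
  expect_equal(nrow(edge), 1L)
  expect_equal(edge$occupancy, 50)
  # an interaction never formed is absent from the table
  expect_false(any(occ$edges$occupancy == 0))
  expect_equal(occ$n_frames, 4L)
})

test_that("graph construction matches exhaustive enumeration on random small systems", {
  crit <- hbond_criteria(3.5, 60, 3L)
  tab <- donor_acceptor_table()
  n_match <- 0L
  for (seed in 1:12) {
    set.seed(seed + 500)
    fr <- random_hbond_system(sample(4:12, 1), sample(3:15, 1), seed)
    hb <- detect_hbonds_frame(fr, tab, crit)
    direct <- hb[!hb$donor_water & !hb$acceptor_water, , drop = FALSE]
    br <- detect_water_bridges(fr, tab, crit, hbonds = hb)
    orc <- oracle_graph(fr, crit)
    expect_identical(unique(pair_keys(data.frame(node_a = direct$donor_res,
                                                 node_b = direct$acceptor_res))),
                     pair_keys(orc$direct))
    expect_identical(pair_keys(br), pair_keys(orc$bridges))
    if (nrow(br) > 0L) {
      key_impl <- paste(pmin(br$node_a, br$node_b),
                        pmax(br$node_a, br$node_b))
      key_orc <- paste(orc$bridges$node_a, orc$bridges$node_b)
      expect_equal(br$n_waters[order(key_impl)],
                   orc$bridges$n_waters[order(key_orc)])
    }
    n_match <- n_match + 1L
  }
  expect_equal(n_match, 12L)
})

test_that("stricter criteria and higher thresholds only remove edges", {
  tab <- donor_acceptor_table()
  for (seed in 31:36) {
    fr <- random_hbond_system(8, 10, seed)
    ens <- frame_to_ensemble(fr)
    occ20 <- accumulate_occupancy(ens, tab, hbond_criteria(3.5, 20))
    occ60 <- accumulate_occupancy(ens, tab, hbond_criteria(3.5, 60))
    # angle nesting at detection level
    expect_true(all(pair_keys(occ20$edges) %in% pair_keys(occ60$edges)))
    # set nesting at equal criteria/threshold
    g1 <- build_graph(occ60, graph_spec(1, 60, 10, allow_override = TRUE))
    g2 <- build_graph(occ60, graph_spec(2, 60, 10, allow_override = TRUE))
    g3 <- build_graph(occ60, graph_spec(3, 60, 10, allow_override = TRUE))
    expect_true(all(pair_keys(g3$edges) %in% pair_keys(g2$edges)))
    expect_true(all(pair_keys(g2$edges) %in% pair_keys(g1$edges)))
    # raising the threshold never adds edges
    lo <- build_graph(occ60, graph_spec(1, 60, 10, allow_override = TRUE))
    hi <- build_graph(occ60, graph_spec(1, 60, 60, allow_override = TRUE))
    expect_true(all(pair_keys(hi$edges) %in% pair_keys(lo$edges)))
  }
})

test_that("graph-set thresholds are validated against the canonical mapping", {
  expect_equal(graph_spec(1, 20)$occupancy_threshold, 10)
  expect_equal(graph_spec(1, 60)$occupancy_threshold, 50)
  expect_equal(graph_spec(2, 60)$occupancy_threshold, 25)
  expect_equal(graph_spec(3, 60)$occupancy_threshold, 15)
  expect_error(graph_spec(3, 60, occupancy_threshold = 40), "inconsistent")
  expect_error(graph_spec("sidechain_direct", 45), "20 or 60")
  expect_silent(graph_spec(3, 60, occupancy_threshold = 40,
                           allow_override = TRUE))
})

test_that("edges are undirected and exports are byte-identical across reruns", {
  fr <- random_hbond_system(8, 8, 77)
  ens <- frame_to_ensemble(fr)
  occ <- accumulate_occupancy(ens)
  expect_true(all(occ$edges$node_a <= occ$edges$node_b))
  g <- build_graph(occ, graph_spec(1, 60, 10, allow_override = TRUE))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  gml <- tempfile(fileext = ".graphml")
  write_hbond_graph(g, csv_path = f1, graphml_path = gml)
  occ_b <- accumulate_occupancy(frame_to_ensemble(fr))
  write_hbond_graph(build_graph(occ_b, graph_spec(1, 60, 10,
                                                  allow_override = TRUE)),
                    csv_path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.size(gml) > 0)
})

test_that("deprotonated residues lose their titratable hydrogens and stop donating", {
  # protonated carboxylate: OD1-HD1 donates to a serine oxygen
  fr <- data.frame(name = c("OD1", "HD1", "OG"),
                   resname = c("ASP", "ASP", "SER"),
                   resno = c(1L, 1L, 2L),
                   x = c(0, 0.98, 2.9), y = 0, z = 0)
  tab <- donor_acceptor_table()
  hb <- detect_hbonds_frame(fr, tab, hbond_criteria())
  expect_true(any(hb$donor_res == "ASP1"))
  fr2 <- apply_protonation_states(fr, c(ASP1 = "deprotonated"), tab)
  expect_false("HD1" %in% fr2$name)
  hb2 <- detect_hbonds_frame(fr2, tab, hbond_criteria())
  expect_false(any(hb2$donor_res == "ASP1"))
  # the bare carboxylate oxygen still accepts
  fr3 <- rbind(fr2, data.frame(name = c("OH", "HH"), resname = "TYR",
                               resno = 3L, x = c(-2.9, -1.92), y = 0, z = 0))
  hb3 <- detect_hbonds_frame(fr3, tab, hbond_criteria())
  expect_true(any(hb3$donor_res == "TYR3" & hb3$acceptor_res == "ASP1"))
})
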