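# two single-atom "ligand" fragments at fixed coordinates
two_point_structure <- function(p, q) {
  atoms <- data.frame(
    serial = 1:2, name = "X1", element = "C", altloc = "",
    resname = "LIG", chain = "L", resseq = 1:2, icode = "",
    x = c(p[1], q[1]), y = c(p[2], q[2]), z = c(p[3], q[3]),
    occupancy = 1, het = TRUE, stringsAsFactors = FALSE)
  new_structure(atoms)
}

test_that("single-linkage distance is the minimum atom-pair distance", {
  s <- two_point_structure(c(0, 0, 0), c(3, 4, 0))
  plan <- build_fragmentation(s)
  expect_equal(min_fragment_distance(plan, s, 1, 2), 5.0)
  expect_equal(min_fragment_distance(plan, s, 2, 1), 5.0)  # symmetric

  # adjacent peptide fragments share the detached Calpha-C bond: their
  # single-linkage distance is that bond length (1.50 A in the fixture)
  t3 <- make_toy_complex(toy_complex_spec(n_chains = 1,
                                          residues_per_chain = 3, seed = 1))
  p3 <- build_fragmentation(t3)
  d12 <- min_fragment_distance(p3, t3, 1, 2)
  expect_equal(d12, 1.50, tolerance = 1e-6)
  expect_lt(d12, 1.8)
})

test_that("min_fragment_distance equals the brute-force oracle", {
  for (seed in 1:50) {
    s <- make_point_structure(n_frags = 2, atoms_per_frag = 1 + seed %% 5,
                              seed = seed)
    plan <- build_fragmentation(s)
    expect_equal(min_fragment_distance(plan, s, 1, 2),
                 oracle_min_dist(plan, s, 1, 2), tolerance = 1e-12)
  }
})

test_that("all_pair_distances returns exactly the pairs within the cutoff", {
  # collinear single-atom fragments at x = 0, 5, 10
  atoms <- data.frame(serial = 1:3, name = "X1", element = "C", altloc = "",
                      resname = "LIG", chain = "L", resseq = 1:3, icode = "",
                      x = c(0, 5, 10), y = 0, z = 0, occupancy = 1, het = TRUE,
                      stringsAsFactors = FALSE)
  s <- new_structure(atoms)
  plan <- build_fragmentation(s)
  d <- all_pair_distances(plan, s, cutoff = 5.4)
  expect_equal(d[, c("i", "j")], data.frame(i = c(1, 2), j = c(2, 3)))

  # a tiny cutoff on separated fragments yields nothing
  expect_equal(nrow(all_pair_distances(plan, s, cutoff = 0.1)), 0)
})

test_that("grid and naive distance backends match the double-loop oracle", {
  for (seed in 1:10) {
    s <- make_point_structure(n_frags = 4 + seed %% 4, atoms_per_frag = 3,
                              seed = 100 + seed)
    plan <- build_fragmentation(s)
    cutoff <- c(3, 5.4, 8)[1 + seed %% 3]
    grid <- all_pair_distances(plan, s, cutoff, backend = "grid")
    naive <- all_pair_distances(plan, s, cutoff, backend = "naive")
    oracle <- oracle_pair_distances(plan, s, cutoff)
    expect_equal(grid, naive, ignore_attr = TRUE)
    expect_equal(grid$i, oracle$i)
    expect_equal(grid$j, oracle$j)
    expect_equal(grid$distance, oracle$distance, tolerance = 1e-12)
  }
})

# a small synthetic analysis set shared by the filter/classify tests
filter_fixture <- function(seed = 21) {
  s <- make_toy_complex(toy_complex_spec(n_chains = 2, residues_per_chain = 6,
                                         n_waters = 2, seed = seed))
  plan <- build_fragmentation(s)
  gen <- make_synthetic_fmo_output(plan, synthetic_pie_spec(
    planted = rbind(planted_pair(2, 8, -12), planted_pair(3, 9, -4.5)),
    seed = seed))
  list(s = s, plan = plan, table = gen$table)
}

test_that("the screen keeps records at the inclusive boundaries", {
  fx <- filter_fixture()
  # hand-made distance table so boundary values are exact
  d <- data.frame(i = c(2, 3), j = c(8, 9), distance = c(5.4, 5.5))
  attr(d, "cutoff") <- 5.5
  tab <- pie_table(data.frame(frag_i = c(2, 3), frag_j = c(8, 9),
                              e_es = c(-3, -20), e_ex = 0, e_ct_mix = 0,
                              e_di = 0, g_sol = 0, total = c(-3, -20)),
                   fx$plan$n_fragments)
  out <- spies_filter(tab, d, fx$plan, spies_params())
  # 5.4 A / -3.0 kcal/mol is retained (inclusive); 5.5 A is dropped
  expect_equal(nrow(out), 1)
  expect_equal(out$frag_i, 2)
  expect_equal(out$pie, -3)
})

test_that("the retained set equals a brute-force predicate scan", {
  fx <- filter_fixture()
  params <- spies_params()
  d <- all_pair_distances(fx$plan, fx$s, cutoff = params$distance_cutoff)
  out <- spies_filter(fx$table, d, fx$plan, params)

  rec <- fx$table$records
  dist_lookup <- stats::setNames(d$distance, paste(d$i, d$j))
  keep <- vapply(seq_len(nrow(rec)), function(r) {
    dd <- dist_lookup[paste(rec$frag_i[r], rec$frag_j[r])]
    !is.na(dd) && dd <= params$distance_cutoff &&
      rec$total[r] <= params$attractive_threshold
  }, logical(1))
  expect_equal(out[, c("frag_i", "frag_j")],
               rec[keep, c("frag_i", "frag_j")], ignore_attr = TRUE)
  expect_equal(out$pie, rec$total[keep])
})

test_that("relaxing either cutoff never removes a retained record", {
  fx <- filter_fixture(seed = 33)
  base_par <- spies_params(distance_cutoff = 4.5,
                           attractive_threshold = -5)
  d_wide <- all_pair_distances(fx$plan, fx$s, cutoff = 10)
  key <- function(df) paste(df$frag_i, df$frag_j)
  base <- spies_filter(fx$table, d_wide, fx$plan, base_par)
  for (dc in c(4.5, 5.4, 7, 10)) {
    for (at in c(-5, -3, -1)) {
      wider <- spies_filter(fx$table, d_wide, fx$plan,
                            spies_params(distance_cutoff = dc,
                                         attractive_threshold = at))
      expect_true(all(key(base) %in% key(wider)),
                  info = sprintf("dc=%g at=%g", dc, at))
    }
  }
  # and a distance table computed below the screening cutoff is refused
  d_narrow <- all_pair_distances(fx$plan, fx$s, cutoff = 3)
  expect_error(spies_filter(fx$table, d_narrow, fx$plan, spies_params()),
               "cutoff")
})

test_that("classification partitions records into the four classes", {
  groups <- c(A = "PD1", B = "PDL1")
  # intra-protein pair on the PD-L1 side
  r1 <- classify_pairs(make_record("LD61", "LR113", "B", "B"), groups)
  expect_equal(r1$iclass, "intra_group")
  # inter-protein pair across the interface
  r2 <- classify_pairs(make_record("I134", "LY123", "A", "B"), groups)
  expect_equal(r2$iclass, "inter_group")
  # water-mediated pair
  r3 <- classify_pairs(make_record("N66", "HOH203", "A", "S",
                                   kind_j = "water"), groups)
  expect_equal(r3$iclass, "water_mediated")
  # water-water pair
  r4 <- classify_pairs(make_record("HOH201", "HOH202", "S", "S",
                                   kind_i = "water", kind_j = "water"),
                       groups)
  expect_equal(r4$iclass, "water_water")
  # unmapped non-water chain is an error
  expect_error(classify_pairs(make_record("X1", "Y2", "A", "Q"), groups),
               "not mapped")

  # partition property: every record gets exactly one class
  fx <- filter_fixture(seed = 44)
  d <- all_pair_distances(fx$plan, fx$s, cutoff = 5.4)
  out <- spies_filter(fx$table, d, fx$plan,
                      spies_params(include_repulsive = TRUE))
  cls <- classify_pairs(out, c(A = "left", B = "right"))
  expect_false(anyNA(cls$iclass))
  expect_true(all(cls$iclass %in% c("inter_group", "intra_group",
                                    "water_mediated", "water_water")))
})

test_that("water bridges arise from two legs across the interface", {
  groups <- c(A = "PD1", B = "PDL1")
  legs <- rbind(
    make_record("I134", "HOH202", "A", "S", kind_j = "water", pie = -6),
    make_record("HOH202", "LY56", "S", "B", kind_i = "water", pie = -4))
  cls <- classify_pairs(legs, groups)
  br <- detect_water_bridges(cls)
  expect_equal(nrow(br), 1)
  expect_equal(br$water, "HOH202")
  expect_setequal(c(br$partner_a, br$partner_b), c("I134", "LY56"))
  expect_setequal(c(br$pie_a, br$pie_b), c(-6, -4))

  # a water bound twice on the same side is no bridge
  same <- rbind(
    make_record("I134", "HOH202", "A", "S", kind_j = "water"),
    make_record("HOH202", "Q75", "S", "A", kind_i = "water"))
  expect_equal(nrow(detect_water_bridges(classify_pairs(same, groups))), 0)
})

test_that("the bridge detector equals exhaustive triple enumeration", {
  groups <- c(A = "G1", B = "G2", C = "G1")
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    rec <- do.call(rbind, lapply(seq_len(n), function(k) {
      if (runif(1) < 0.6) {
        w <- paste0("HOH", 200 + sample(3, 1))
        p <- paste0("R", sample(6, 1))
        ch <- sample(c("A", "B", "C"), 1)
        make_record(w, p, "S", ch, kind_i = "water", pie = -runif(1, 3, 9))
      } else {
        make_record(paste0("R", sample(6, 1)), paste0("R", sample(6, 1) + 6),
                    sample(c("A", "B", "C"), 1), sample(c("A", "B", "C"), 1),
                    pie = -runif(1, 3, 9))
      }
    }))
    cls <- classify_pairs(rec, groups)
    got <- detect_water_bridges(cls)
    want <- oracle_bridges(cls)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      ka <- paste(got$group_a, got$partner_a)
      kb <- paste(got$group_b, got$partner_b)
      got_keys <- sort(paste(got$water, pmin(ka, kb), pmax(ka, kb)))
      want_keys <- sort(paste(want$water, want$key_a, want$key_b))
      expect_equal(got_keys, want_keys)
    }
  }
})

test_that("hot-spot regions split residue runs at the gap tolerance", {
  groups <- c(A = "PD1", B = "PDL1")
  mk <- function(rs) do.call(rbind, lapply(rs, function(r)
    make_record(paste0("R", r), "LX1", "A", "B", resseq_i = r, resseq_j = 1)))
  cls <- classify_pairs(mk(c(132, 133, 134, 136)), groups)
  hs <- hotspot_regions(cls, "PD1", gap_tolerance = 2)
  expect_equal(nrow(hs), 1)
  expect_equal(c(hs$start, hs$end), c(132, 136))
  expect_equal(hs$support, 4)

  cls2 <- classify_pairs(mk(c(66, 75)), groups)
  hs2 <- hotspot_regions(cls2, "PD1", gap_tolerance = 2)
  expect_equal(nrow(hs2), 2)

  # no inter-group records: empty result
  intra <- classify_pairs(make_record("R1", "R5", "A", "A"), groups)
  expect_equal(nrow(hotspot_regions(intra, "PD1")), 0)
})

test_that("the published wild-type pair list maps to 10 partner residues", {
  ppi <- utils::read.csv(system.file("extdata", "pd1_pdl1_reported_ppi.csv",
                                     package = "spies3d"))
  expect_equal(nrow(ppi), 13)
  rec <- do.call(rbind, lapply(seq_len(nrow(ppi)), function(k)
    make_record(ppi$pd1_label[k], paste0("L", ppi$pdl1_label[k]), "A", "B",
                resseq_i = ppi$pd1_resseq[k], resseq_j = ppi$pdl1_resseq[k])))
  cls <- classify_pairs(rec, c(A = "PD1", B = "PDL1"))
  hs <- hotspot_regions(cls, "PDL1", gap_tolerance = 2)
  expect_equal(sum(hs$n_residues), 10)
  # PD-1 side touches 7 distinct residues
  expect_equal(sum(hotspot_regions(cls, "PD1", 2)$n_residues), 7)
})

test_that("interaction maps count per-residue commonality across complexes", {
  groups <- c(A = "T", B = "P")
  hit <- function(rs) classify_pairs(do.call(rbind, lapply(rs, function(r)
    make_record(paste0("R", r), "X1", "A", "B", resseq_i = r,
                resseq_j = 1))), groups)
  m <- build_interaction_map(list(c1 = hit(c(10, 20)), c2 = hit(10)), "T")
  expect_equal(unname(m$commonality[m$residues$resseq == 10]), 2)
  expect_equal(unname(m$commonality[m$residues$resseq == 20]), 1)

  # an empty record set is an all-false column
  empty <- hit(10)[0, ]
  m2 <- build_interaction_map(list(c1 = hit(10), c2 = empty), "T")
  expect_false(any(m2$presence[, "c2"]))

  # five synthetic "antibody" sets sharing exactly two residues
  sets <- lapply(1:5, function(k) hit(c(56, 58, 100 + k)))
  names(sets) <- paste0("ab", 1:5)
  m5 <- build_interaction_map(sets, "T")
  expect_setequal(m5$residues$resseq[m5$commonality == 5], c(56, 58))

  # inconsistent labels for one residue number across complexes: error
  bad <- hit(10)
  bad$label_i <- "Q10"
  expect_error(build_interaction_map(list(c1 = hit(10), c2 = bad), "T"),
               "inconsistent")
})

test_that("scatter export serializes records losslessly to JSON", {
  fx <- filter_fixture(seed = 55)
  d <- all_pair_distances(fx$plan, fx$s, cutoff = 5.4)
  rec <- classify_pairs(spies_filter(fx$table, d, fx$plan,
                                     spies_params(include_repulsive = TRUE)),
                        c(A = "left", B = "right"))
  sc <- export_scatter(rec)
  expect_equal(nrow(sc), nrow(rec))
  expect_equal(sc$z, rec$distance)
  expect_equal(sc$value, rec$pie)
  back <- jsonlite::fromJSON(scatter_json(sc))
  expect_equal(back$z, sc$z)
  expect_equal(back$value, sc$value)
  expect_equal(back$x, sc$x)

  # zero records still serialize to valid JSON
  empty <- export_scatter(rec[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(jsonlite::validate(scatter_json(empty)))
})
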