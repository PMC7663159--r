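# duplex construction: builder, strand flip, isoguanine, modified pair,
# neutralization, constraint-pair selection

test_that("antiparallel builder produces complementary pairs on an ideal helix", {
  d <- build_antiparallel_duplex("GAAAGATAGGGAG", rise = 3.38, twist = 36)
  expect_equal(nrow(d$pairing), 13L)
  expect_equal(nrow(d$units), 26L)
  expect_identical(d$orientation, "antiparallel")

  d1 <- build_antiparallel_duplex("A")
  expect_equal(nrow(d1$pairing), 1L)
  expect_identical(sort(d1$units$base_code), c("A", "T"))

  # consecutive C1'-C1' axial separation equals the rise exactly
  d2 <- build_antiparallel_duplex("GC", rise = 3.38, twist = 36)
  a <- d2$atoms
  z1 <- a$z[a$site == "C1'" & a$unit_id %in%
              d2$units$unit_id[d2$units$strand == 1 & d2$units$level == 1]]
  z2 <- a$z[a$site == "C1'" & a$unit_id %in%
              d2$units$unit_id[d2$units$strand == 1 & d2$units$level == 2]]
  expect_equal(abs(z2 - z1), 3.38, tolerance = 1e-9)

  expect_error(build_antiparallel_duplex("GAXAG"), "X")
  expect_error(build_antiparallel_duplex(""), "nonempty")
})

test_that("strand flip yields a complementary parallel duplex with Fig-6 numbering", {
  d <- parallelize(build_antiparallel_duplex("GAGGGATAGAAAG"))
  expect_identical(d$orientation, "parallel")
  expect_identical(d$pairing$strand2_pos, d$pairing$strand1_pos)
  # strand 2 read 5'->3' is the position-wise complement
  u2 <- d$units[d$units$strand == 2, ]
  expect_identical(paste(u2$base_code[order(u2$pos5to3)], collapse = ""),
                   "CTCCCTATCTTTC")
  # the strand-2 unit at level 7 is residue 20 (pairs T7)
  u7 <- d$units[d$units$level == 7, ]
  expect_setequal(u7$resid, c(7L, 20L))
  expect_identical(u7$base_code[u7$strand == 1], "T")
  # both strands run 5'->3' along +z
  for (s in 1:2) {
    us <- d$units[d$units$strand == s, ]
    us <- us[order(us$pos5to3), ]
    zs <- us$level * d$rise
    expect_true(all(diff(zs) > 0))
  }
  expect_error(parallelize(d), "already parallel")

  # 1-bp duplex: identical pairing, flipped strand indexing
  d1 <- parallelize(build_antiparallel_duplex("A"))
  expect_equal(d1$pairing$strand2_pos, 1L)
})

test_that("guanine->isoguanine swaps the exocyclic groups and is an involution", {
  d <- parallelize(build_antiparallel_duplex("GAGGGATAGAAAG"))
  di <- guanine_to_isoguanine(d)
  expect_equal(sum(di$units$base_code == "iG"), 6L)
  u1 <- di$units[di$units$strand == 1, ]
  expect_identical(
    paste(ifelse(u1$base_code[order(u1$pos5to3)] == "iG", "iG",
                 u1$base_code[order(u1$pos5to3)]), collapse = ""),
    "iGAiGiGiGATAiGAAAiG")
  expect_true(all(di$pairing$pair_class[di$pairing$pair_class != "AT"] ==
                    "iGC"))
  # involution: coordinates restored exactly
  dback <- guanine_to_isoguanine(di)
  expect_equal(dback$atoms$x, d$atoms$x)
  expect_equal(dback$atoms$y, d$atoms$y)
  expect_identical(dback$units$base_code, d$units$base_code)
  # no G: identity
  dnog <- build_antiparallel_duplex("ATA")
  expect_identical(guanine_to_isoguanine(dnog)$atoms,
                   dnog$atoms)
})

test_that("modified-pair insertion places two Hg with two acceptors each", {
  d <- guanine_to_isoguanine(parallelize(
    build_antiparallel_duplex("GAGGGATAGAAAG")))
  dm <- insert_modified_pair(d, 7)
  expect_identical(
    dm$pairing$pair_class[dm$pairing$level == 7], "modified")
  ea <- dm$units[dm$units$base_code == "eA", ]
  expect_equal(ea$resid, 20L)
  hg <- dm$atoms[dm$atoms$element == "Hg", ]
  expect_equal(nrow(hg), 2L)
  # acceptor sites within 2.5 A of each Hg: exactly two
  base_acc <- dm$atoms[!is.na(dm$atoms$unit_id) &
                         dm$atoms$element %in% c("N", "O"), ]
  for (r in seq_len(2)) {
    dist <- sqrt((base_acc$x - hg$x[r])^2 + (base_acc$y - hg$y[r])^2 +
                   (base_acc$z - hg$z[r])^2)
    expect_equal(sum(dist <= 2.5), 2L)
  }
  # base-pair moiety charge: deprotonated T (-1) + 2 Hg2+ = +3
  mod_units <- dm$units$unit_id[dm$units$level == 7]
  qpair <- sum(dm$atoms$charge[(dm$atoms$unit_id %in% mod_units &
                                  dm$atoms$site != "P") |
                                 dm$atoms$element == "Hg"])
  expect_equal(qpair, 3)

  # Hg-free, protonated analogue
  dm3 <- insert_modified_pair(d, 7, modified_pair_template(hg = FALSE))
  expect_equal(sum(dm3$atoms$element == "Hg"), 0L)
  expect_true("H3" %in% dm3$atoms$site[dm3$atoms$unit_id %in%
                                         .subset2(dm3$units, "unit_id")])

  expect_error(insert_modified_pair(d, 1), "not A:T")
})

test_that("neutralization arithmetic and determinism", {
  d <- default_duplex(neutralized = FALSE)
  expect_equal(duplex_net_charge(d), -23L)   # 26 phosphates, +3 pair
  dn <- neutralize(d, seed = 5)
  expect_equal(sum(dn$atoms$site == "Na+"), 23L)
  expect_equal(duplex_net_charge(dn), 0L)
  # ions keep a 3 A exclusion shell
  ion <- dn$atoms[dn$atoms$site == "Na+", ]
  other <- dn$atoms[dn$atoms$site != "Na+", ]
  for (r in seq_len(nrow(ion))) {
    expect_gte(min(sqrt((other$x - ion$x[r])^2 + (other$y - ion$y[r])^2 +
                          (other$z - ion$z[r])^2)), 3)
  }
  # identical seed -> bit-identical model
  dn2 <- neutralize(d, seed = 5)
  expect_identical(dn$atoms, dn2$atoms)
  # zero-charge input: no ions added
  expect_identical(neutralize(dn, seed = 1), dn)

  # structure-3 route: delete Hg + protonate from the neutral system,
  # then three further cations rebalance the -3
  d3 <- remove_hg(dn)
  expect_equal(duplex_net_charge(d3), -3L)
  d3n <- neutralize(d3, seed = 6)
  expect_equal(sum(d3n$atoms$site == "Na+"), 26L)
  expect_equal(duplex_net_charge(d3n), 0L)
})

test_that("constraint-pair selection: variants, counts, non-overlap, fallback", {
  d <- default_duplex()
  sdna <- select_constraint_pairs(d, "DNA")
  expect_equal(nrow(sdna$pairs), 14L)   # 12 regular N...H + 2 Hg N...O
  sequi <- select_constraint_pairs(d, "EQUI")
  expect_equal(nrow(sequi$pairs), 30L)  # 6 AT x 2 + 6 iGC x 3
  siso <- select_constraint_pairs(d, "ISO")
  expect_equal(nrow(siso$pairs), 2L)
  # non-overlap is structural: every atom index unique
  for (s in list(sdna, sequi, siso)) {
    expect_false(anyDuplicated(as.vector(s$pairs)) > 0)
  }
  # built geometry sits at the hydrogen-bond distances the zip protocol
  # expects
  conf <- duplex_configuration(d)
  expect_equal(dynamic_distance(sequi, conf), 1.9, tolerance = 0.02)
  # ISO distance spans the two Hg bridges
  expect_equal(dynamic_distance(siso, conf), 4.3, tolerance = 1e-6)

  # Hg-free model: DNA/ISO fall back to the donor-acceptor pairs
  d3 <- remove_hg(d)
  expect_message(s3 <- select_constraint_pairs(d3, "ISO"), "no Hg")
  expect_equal(nrow(s3$pairs), 2L)

  expect_error(select_constraint_pairs(
    parallelize(build_antiparallel_duplex("AT")), "ISO"), "modified")
})
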