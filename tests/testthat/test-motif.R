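test_that("the planted Walker A triple is recovered on the ideal site", {
  out <- build_ideal_site(site_blueprint())
  m <- out$model
  s <- find_nucleotide_sites(m)[[1]]
  wa <- find_walker_a(s, m)
  expect_equal(wa$lys_wa$resno[1], out$truth$lys_wa)
  expect_equal(wa$k_plus_1$resno[1], out$truth$k_plus_1)
  expect_equal(wa$k_minus_3$resno[1], out$truth$k_minus_3)
  expect_false(wa$k1_not_st)
})

test_that("the nearest qualifying lysine wins, by brute force", {
  out <- build_ideal_site(site_blueprint())
  m <- out$model
  a <- m$atoms
  o1b <- as.numeric(a[a$resno == 302L & a$elety == "O1B", c("x", "y", "z")])
  # plant a second lysine whose NZ is 4.5 A from O1B (farther than the 3.0 A
  # planted one), complete with backbone so it is a real chain residue
  u <- c(0.1, 0.8, 0.6); u <- u / sqrt(sum(u^2))
  nz2 <- o1b + 4.5 * u
  extra <- a[a$resno == 229L & !a$het, ]
  extra$resno <- 150L
  sel <- extra$elety == "NZ"
  shift <- nz2 - as.numeric(extra[sel, c("x", "y", "z")])
  extra[, c("x", "y", "z")] <- sweep(as.matrix(extra[, c("x", "y", "z")]),
                                     2, shift, "+")
  m$atoms <- rbind(a, extra)
  s <- find_nucleotide_sites(m)[[1]]
  wa <- find_walker_a(s, m)
  # brute-force oracle: min over all Lys NZ to beta-O distances
  bo <- a[a$resno == 302L & a$elety %in% c("O1B", "O2B", "O3B"), ]
  nzs <- m$atoms[m$atoms$resid == "LYS" & m$atoms$elety == "NZ", ]
  dmin <- apply(as.matrix(nzs[, c("x", "y", "z")]), 1, function(p)
    min(sqrt(colSums((t(as.matrix(bo[, c("x", "y", "z")])) - p)^2))))
  expect_equal(wa$lys_wa$resno[1], nzs$resno[which.min(dmin)])
  expect_equal(wa$lys_wa$resno[1], 229L)
})

test_that("a site with no lysine near the beta-phosphate is rejected", {
  out <- build_ideal_site(site_blueprint())
  m <- out$model
  m$atoms <- m$atoms[!(m$atoms$resno == 229L & m$atoms$elety == "NZ"), ]
  s <- find_nucleotide_sites(m)[[1]]
  ann <- annotate_site(s, m)
  expect_equal(ann$rejected, "no P-loop Lys")
})

test_that("a kinase-like glycine at K+1 raises the warning flag", {
  out <- build_ideal_site(site_blueprint(k1_residue = "GLY"))
  m <- out$model
  s <- find_nucleotide_sites(m)[[1]]
  ann <- annotate_site(s, m)
  expect_true(ann$k1_not_st)
  expect_null(ann$wb_residue)    # no hydroxyl to search from
})

test_that("Walker B selection follows the hydrophobic-window rule", {
  # planted hydrophobic window: primary rule, no fallback
  out <- build_ideal_site(site_blueprint())
  m <- out$model
  s <- find_nucleotide_sites(m)[[1]]
  ann <- annotate_site(s, m)
  expect_equal(ann$wb_residue$resno[1], 270L)
  expect_false(ann$wb_fallback)
  expect_equal(ann$wb_distance, 2.6, tolerance = 1e-6)

  # nearer decoy with an ionizable residue in its window loses to the
  # farther Asp with a clean window
  out2 <- build_ideal_site(site_blueprint(wb_k1_target = 3.4,
                                          wb_decoy_dist = 2.8))
  m2 <- out2$model
  s2 <- find_nucleotide_sites(m2)[[1]]
  ann2 <- annotate_site(s2, m2)
  expect_equal(ann2$wb_residue$resno[1], 270L)
  expect_false(ann2$wb_fallback)

  # all candidates fail the window: nearest returned with the fallback flag
  out3 <- build_ideal_site(site_blueprint(wb_window = c("LEU", "SER", "VAL")))
  m3 <- out3$model
  ann3 <- annotate_site(find_nucleotide_sites(m3)[[1]], m3)
  expect_equal(ann3$wb_residue$resno[1], 270L)
  expect_true(ann3$wb_fallback)

  # no candidate within 5 A: absent
  out4 <- build_ideal_site(site_blueprint(wb_k1_target = 5.5))
  ann4 <- annotate_site(find_nucleotide_sites(out4$model)[[1]], out4$model)
  expect_null(ann4$wb_residue)
})

test_that("Walker B agrees with an independent brute-force oracle", {
  cases <- list(
    site_blueprint(seed = 1),
    site_blueprint(wb_k1_target = 3.4, wb_decoy_dist = 2.8, seed = 2),
    site_blueprint(wb_window = c("LEU", "SER", "VAL"), seed = 3),
    site_blueprint(wb_decoy_dist = 2.3, seed = 4),
    site_blueprint(wb_k1_target = 2.9, wb_decoy_dist = 3.2, jitter_sd = 0.05,
                   seed = 5))
  for (bp in cases) {
    out <- build_ideal_site(bp)
    m <- out$model
    ann <- annotate_site(find_nucleotide_sites(m)[[1]], m)
    oracle <- brute_walker_b(m, "A", 230L)
    expect_equal(ann$wb_residue$resno[1], oracle$resno)
    expect_equal(ann$wb_fallback, oracle$fallback)
  }
})

test_that("with an empty ionizable set the rule degenerates to nearest", {
  out <- build_ideal_site(site_blueprint(wb_k1_target = 3.4,
                                         wb_decoy_dist = 2.8))
  m <- out$model
  oracle <- brute_walker_b(m, "A", 230L, ionizable = character(0))
  expect_equal(oracle$resno, 280L)   # nearest carboxylate, window ignored
  expect_false(oracle$fallback)
})

test_that("Switch I is found at shell position #3 and absent when water", {
  out <- build_ideal_site(site_blueprint(include_switch_i = TRUE))
  m <- out$model
  s <- find_nucleotide_sites(m)[[1]]
  ann <- annotate_site(s, m)
  expect_equal(ann$switch_i$resno[1], 251L)
  expect_equal(ann$shell$ligands$resno[ann$shell$ligands$pos == "3"], 251L)

  out2 <- build_ideal_site(site_blueprint(include_switch_i = FALSE))
  ann2 <- annotate_site(find_nucleotide_sites(out2$model)[[1]], out2$model)
  expect_null(ann2$switch_i)
})

test_that("Switch I recovery is stable under jitter", {
  for (seed in 1:20) {
    out <- build_ideal_site(site_blueprint(include_switch_i = TRUE,
                                           jitter_sd = 0.1, seed = seed))
    ann <- annotate_site(find_nucleotide_sites(out$model)[[1]], out$model)
    expect_equal(ann$switch_i$resno[1], 251L, label = paste("seed", seed))
  }
})

test_that("the apical water maximising the in-line angle is selected", {
  out <- build_ideal_site(site_blueprint(wcat_angle = 170, wcat_dist = 3.2))
  m <- out$model
  s <- find_nucleotide_sites(m)[[1]]
  w <- find_wcat(s, m)
  expect_equal(w$resno, 410L)

  # a water placed at 90 degrees only: below the 140-degree threshold
  out2 <- build_ideal_site(site_blueprint(wcat_angle = 90))
  s2 <- find_nucleotide_sites(out2$model)[[1]]
  expect_null(find_wcat(s2, out2$model))

  # two candidate waters at 150 and 165 degrees: the 165-degree one wins,
  # as a brute-force scan over all waters confirms
  m3 <- build_ideal_site(site_blueprint(wcat_angle = 150))$model
  w165 <- build_ideal_site(site_blueprint(wcat_angle = 165))$model
  extra <- w165$atoms[w165$atoms$resno == 410L, ]
  extra$resno <- 411L
  m3$atoms <- rbind(m3$atoms, extra)
  s3 <- find_nucleotide_sites(m3)[[1]]
  expect_equal(find_wcat(s3, m3)$resno, 411L)
})

test_that("vanadate supplies its apical oxygen as the W_cat surrogate", {
  out <- build_ideal_site(site_blueprint(gamma_moiety = "VO4"))
  m <- out$model
  s <- find_nucleotide_sites(m)[[1]]
  w <- find_wcat(s, m)
  expect_equal(w$resid, "VO4")
  expect_equal(w$elesy, "O")
})

test_that("W_cat polar contacts list N/O atoms within 3.6 A, carboxylate first", {
  out <- build_ideal_site(site_blueprint(cat_carboxylate_dist = 2.8))
  m <- out$model
  s <- find_nucleotide_sites(m)[[1]]
  ann <- annotate_site(s, m)
  expect_equal(ann$catalytic_carboxylate$resno[1], 290L)
  expect_true(any(ann$wcat_contacts$resid == "GLU" &
                    abs(ann$wcat_contacts$distance - 2.8) < 0.01))

  # add a second carboxylate at 3.4 A: both listed, the nearer Glu still wins
  oe <- as.numeric(m$atoms[m$atoms$resno == 410L, c("x", "y", "z")]) +
    3.4 * c(0.55, 0.55, 0.63) / sqrt(sum(c(0.55, 0.55, 0.63)^2))
  m$atoms <- rbind(m$atoms, data.frame(
    chain = "A", resno = 295L, insert = "", resid = "ASP",
    elety = "OD1", elesy = "O", x = oe[1], y = oe[2], z = oe[3],
    o = 1, alt = "", het = FALSE))
  ann2 <- annotate_site(find_nucleotide_sites(m)[[1]], m)
  expect_true(any(ann2$wcat_contacts$resid == "ASP" &
                    abs(ann2$wcat_contacts$distance - 3.4) < 0.01))
  expect_equal(ann2$catalytic_carboxylate$resno[1], 290L)
  expect_false(is.unsorted(ann2$wcat_contacts$distance))

  # no polar atom in range: empty contact list
  out3 <- build_ideal_site(site_blueprint())
  ann3 <- annotate_site(find_nucleotide_sites(out3$model)[[1]], out3$model)
  expect_equal(nrow(ann3$wcat_contacts), 0L)
  expect_null(ann3$catalytic_carboxylate)
})

test_that("annotation recovery holds under moderate jitter", {
  for (seed in 1:20) {
    out <- build_ideal_site(site_blueprint(jitter_sd = 0.15, seed = seed))
    m <- out$model
    ann <- annotate_site(find_nucleotide_sites(m)[[1]], m)
    expect_equal(ann$lys_wa$resno[1], out$truth$lys_wa)
    expect_equal(ann$k_plus_1$resno[1], out$truth$k_plus_1)
    expect_equal(ann$wb_residue$resno[1], out$truth$wb)
  }
})
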