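mk_res <- function(resno, resid, elety, xyz, chain = "A") {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, elesy = substr(elety, 1, 1), x = xyz[, 1],
             y = xyz[, 2], z = xyz[, 3], o = 1, alt = "", het = FALSE)
}

test_that("the Walker-B-to-K+1 distance is the carboxylate/hydroxyl minimum", {
  ann <- list(wb_residue = mk_res(1, "ASP", c("OD1", "OD2"),
                                  c(0, 0, 2.5, 0, 0, 99)),
              k_plus_1 = mk_res(2, "SER", "OG", c(0, 0, 0)))
  expect_equal(wb_k1_distance(ann), 2.50)

  ann2 <- list(wb_residue = mk_res(1, "ASP", c("OD1", "OD2"),
                                   c(3.1, 0, 0, 2.6, 0, 0)),
               k_plus_1 = mk_res(2, "THR", "OG1", c(0, 0, 0)))
  expect_equal(wb_k1_distance(ann2), 2.60)

  expect_true(is.na(wb_k1_distance(list(wb_residue = NULL,
                                        k_plus_1 = ann2$k_plus_1))))
})

test_that("the K-3 amide-to-gamma distance uses the nearest gamma O or F", {
  out <- build_ideal_site(site_blueprint())
  m <- out$model
  s <- find_nucleotide_sites(m)[[1]]
  ann <- annotate_site(s, m)
  expect_equal(hnk3_gamma_distance(ann, s), out$truth$hnk3_o2g,
               tolerance = 1e-6)

  # with an AlF4 mimic the fluorines stand in for the gamma oxygens
  out2 <- build_ideal_site(site_blueprint(gamma_moiety = "ALF4"))
  s2 <- find_nucleotide_sites(out2$model)[[1]]
  ann2 <- annotate_site(s2, out2$model)
  d2 <- hnk3_gamma_distance(ann2, s2)
  expect_equal(d2, out2$truth$hnk3_o2g, tolerance = 0.01)
  # brute force over all peripheral atoms
  a <- out2$model$atoms
  n <- as.numeric(a[a$resno == 226L & a$elety == "N", c("x", "y", "z")])
  fl <- a[a$resno == 303L & a$elesy == "F", c("x", "y", "z")]
  expect_equal(d2, round(min(sqrt(colSums((t(as.matrix(fl)) - n)^2))), 2))

  # no gamma moiety: NA
  out3 <- build_ideal_site(site_blueprint(gamma_moiety = "none"))
  s3 <- find_nucleotide_sites(out3$model)[[1]]
  expect_true(is.na(hnk3_gamma_distance(annotate_site(s3, out3$model), s3)))
})

test_that("the ideal octahedral shell has 12 edges of b*sqrt(2) at 90 degrees", {
  out <- build_ideal_site(site_blueprint(mg_bond_length = 2.1))
  m <- out$model
  s <- find_nucleotide_sites(m)[[1]]
  ann <- annotate_site(s, m)
  shell <- ann$shell
  expect_true(shell$complete)
  expect_length(shell$edges, 12L)
  expect_equal(shell$edges, rep(2.1 * sqrt(2), 12), tolerance = 1e-6)
  # all twelve edges within the 2.9-3.0 A proton-transfer range for
  # Mg-O bonds in the usual 2.05-2.12 A window
  for (b in c(2.05, 2.08, 2.12)) {
    o <- build_ideal_site(site_blueprint(mg_bond_length = b))
    sh <- annotate_site(find_nucleotide_sites(o$model)[[1]], o$model)$shell
    expect_true(all(sh$edges >= 2.89 & sh$edges <= 3.01), label = paste("b =", b))
  }
})

test_that("shell position labels match the generator's ground truth", {
  for (bp in list(site_blueprint(), site_blueprint(include_switch_i = TRUE),
                  site_blueprint(gamma_moiety = "ALF4"))) {
    out <- build_ideal_site(bp)
    m <- out$model
    ann <- annotate_site(find_nucleotide_sites(m)[[1]], m)
    lg <- ann$shell$ligands
    got <- lg$resno[match(out$truth$shell$pos, lg$pos)]
    expect_equal(got, out$truth$shell$resno)
  }
})

test_that("a deleted shell water leaves an incomplete 5-ligand shell", {
  out <- build_ideal_site(site_blueprint())
  m <- out$model
  m$atoms <- m$atoms[m$atoms$resno != 402L, ]
  ann <- annotate_site(find_nucleotide_sites(m)[[1]], m)
  expect_equal(nrow(ann$shell$ligands), 5L)
  expect_false(ann$shell$complete)
})

test_that("shell membership is stable under jitter", {
  for (seed in 1:20) {
    out <- build_ideal_site(site_blueprint(jitter_sd = 0.1, seed = seed))
    m <- out$model
    ann <- annotate_site(find_nucleotide_sites(m)[[1]], m)
    expect_equal(sort(paste(ann$shell$ligands$resno, ann$shell$ligands$elety)),
                 sort(c("302 O2B", "302 O1G", "230 OG1", "401 O", "402 O",
                        "403 O")), label = paste("seed", seed))
  }
})

test_that("hydrogen bonds classify as short/typical/long with stated bounds", {
  expect_equal(classify_hbond(c(2.5, 2.7, 2.9, 3.2, 3.3)),
               c("short", "typical", "typical", "typical", "long"))
  expect_error(classify_hbond(0), "positive")
  # piecewise-constant and monotone: decreasing d never leaves short
  grid <- seq(2.2, 3.6, by = 0.01)
  cls <- classify_hbond(grid)
  expect_true(all(diff(match(cls, c("short", "typical", "long"))) >= 0))
})

test_that("the pKa-mismatch calibration passes through its anchors", {
  expect_equal(delta_pka_estimate(2.4), 0)
  expect_equal(delta_pka_estimate(2.9), 20)
  expect_equal(delta_pka_estimate(2.65), 10)
  expect_equal(delta_pka_estimate(2.2), 0)    # clamped
  expect_equal(delta_pka_estimate(3.5), 20)   # clamped
  g <- delta_pka_estimate(seq(1, 4, by = 0.05))
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g <= 20))
})

test_that("P-loop superposition is exact for rigid copies and honest for jitter", {
  out <- build_ideal_site(site_blueprint())
  m <- out$model
  ann <- annotate_site(find_nucleotide_sites(m)[[1]], m)
  self <- superpose_ploop(list(model = m, annotation = ann),
                          list(model = m, annotation = ann))
  expect_lt(self$rmsd, 1e-9)

  m2 <- rotate_model(m)
  ann2 <- annotate_site(find_nucleotide_sites(m2)[[1]], m2)
  rot <- superpose_ploop(list(model = m2, annotation = ann2),
                         list(model = m, annotation = ann))
  expect_lt(rot$rmsd, 1e-9)

  # jittered copy: RMSD reflects the applied noise
  sdj <- 0.1
  rmsds <- vapply(1:10, function(seed) {
    mj <- m
    set.seed(seed)
    n <- nrow(mj$atoms)
    mj$atoms$x <- mj$atoms$x + rnorm(n, 0, sdj)
    mj$atoms$y <- mj$atoms$y + rnorm(n, 0, sdj)
    mj$atoms$z <- mj$atoms$z + rnorm(n, 0, sdj)
    annj <- annotate_site(find_nucleotide_sites(mj)[[1]], mj)
    superpose_ploop(list(model = mj, annotation = annj),
                    list(model = m, annotation = ann))$rmsd
  }, numeric(1))
  expect_true(all(rmsds > 0.05 & rmsds < 0.25))

  # invariance under a pre-applied rigid motion of the mobile structure
  m3 <- rotate_model(m, angle = 0.4, shift = c(-3, 9, 5))
  ann3 <- annotate_site(find_nucleotide_sites(m3)[[1]], m3)
  mj <- m3
  set.seed(42)
  n <- nrow(mj$atoms)
  mj$atoms$x <- mj$atoms$x + rnorm(n, 0, sdj)
  annj <- annotate_site(find_nucleotide_sites(mj)[[1]], mj)
  r1 <- superpose_ploop(list(model = mj, annotation = annj),
                        list(model = m, annotation = ann))$rmsd
  mjr <- rotate_model(mj, angle = 1.1, shift = c(8, 1, -4))
  annjr <- annotate_site(find_nucleotide_sites(mjr)[[1]], mjr)
  r2 <- superpose_ploop(list(model = mjr, annotation = annjr),
                        list(model = m, annotation = ann))$rmsd
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("superposition RMSD matches the bio3d reference", {
  out <- build_ideal_site(site_blueprint())
  m <- out$model
  ann <- annotate_site(find_nucleotide_sites(m)[[1]], m)
  mj <- rotate_model(m)
  set.seed(9)
  n <- nrow(mj$atoms)
  mj$atoms$x <- mj$atoms$x + rnorm(n, 0, 0.2)
  annj <- annotate_site(find_nucleotide_sites(mj)[[1]], mj)
  ours <- superpose_ploop(list(model = mj, annotation = annj),
                          list(model = m, annotation = ann))
  # same backbone window, independently superposed with bio3d
  grab <- function(mm) {
    a <- mm$atoms
    a <- a[a$resno %in% 217:236 & a$elety %in% c("N", "CA", "C", "O") &
             !a$het, ]
    a <- a[order(a$resno, match(a$elety, c("N", "CA", "C", "O"))), ]
    as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  }
  xyz_m <- grab(mj); xyz_r <- grab(m)
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_r, mobile = xyz_m))
  ref_rmsd <- sqrt(mean(colSums(matrix((fitted - xyz_r)^2, nrow = 3))))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("the contact inventory matches a quadratic all-pairs oracle", {
  out <- build_ideal_site(site_blueprint(gamma_moiety = "ALF4",
                                         cat_carboxylate_dist = 2.8))
  m <- out$model
  s <- find_nucleotide_sites(m)[[1]]
  ann <- annotate_site(s, m)
  inv <- contact_inventory(s, ann, m)
  # oracle: brute-force over every (gamma-side atom x protein N/O) pair
  a <- m$atoms
  src <- rbind(a[a$resno == 303L, ],
               a[a$resno == 410L & a$resid == "HOH", ])
  prot <- a[!a$het & a$elesy %in% c("N", "O"), ]
  cnt <- 0L
  for (i in seq_len(nrow(src))) {
    d <- sqrt((prot$x - src$x[i])^2 + (prot$y - src$y[i])^2 +
                (prot$z - src$z[i])^2)
    cnt <- cnt + sum(d <= 3.6)
  }
  expect_equal(nrow(inv), cnt)
  expect_true(all(inv$strength[inv$distance <= 3.2] == "moderate"))
  expect_true(all(inv$strength[inv$distance > 3.2] == "weak"))
})

test_that("hand-planted moderate and weak lysine contacts are both counted", {
  # an AlF4 moiety with two fluorine-to-NZ contacts, one moderate, one weak
  out <- build_ideal_site(site_blueprint(gamma_moiety = "ALF4"))
  m <- out$model
  a <- m$atoms
  fl <- a[a$resno == 303L & a$elesy == "F", ]
  f1 <- as.numeric(fl[1, c("x", "y", "z")])
  f2 <- as.numeric(fl[2, c("x", "y", "z")])
  # move the planted NZ to 2.9 A from one F and check the second distance
  u <- c(0.3, 0.8, 0.53); u <- u / sqrt(sum(u^2))
  nz <- f1 + 2.9 * u
  m$atoms[m$atoms$resno == 229L & m$atoms$elety == "NZ", c("x", "y", "z")] <-
    matrix(nz, 1)
  s <- find_nucleotide_sites(m)[[1]]
  ann <- annotate_site(s, m)
  inv <- contact_inventory(s, ann, m)
  kv <- inv[inv$atom == "NZ", ]
  expect_true(any(kv$strength == "moderate" & abs(kv$distance - 2.9) < 0.05))
})

test_that("the beta-phosphate-to-Pi distance is the planted O-O minimum", {
  out <- build_ideal_site(site_blueprint(gamma_moiety = "Pi",
                                         pi_beta_target = 2.45))
  m <- out$model
  s <- find_nucleotide_sites(m)[[1]]
  bpi <- beta_pi_distance(s, m)
  expect_equal(bpi$distance, 2.45, tolerance = 0.01)
  expect_true(bpi$bonding)
  # brute-force all-pairs oracle
  a <- m$atoms
  bo <- a[a$resno == 302L & a$elety %in% c("O1B", "O2B", "O3B"), ]
  po <- a[a$resno == 304L & a$elesy == "O", ]
  dm <- outer(seq_len(nrow(bo)), seq_len(nrow(po)), Vectorize(function(i, j)
    sqrt((bo$x[i] - po$x[j])^2 + (bo$y[i] - po$y[j])^2 + (bo$z[i] - po$z[j])^2)))
  expect_equal(bpi$distance, round(min(dm), 2))

  # a far-away phosphate is still measured but flagged non-bonding
  sel <- m$atoms$resno == 304L
  m$atoms[sel, "x"] <- m$atoms[sel, "x"] + 10
  s2 <- find_nucleotide_sites(m)[[1]]
  bpi2 <- beta_pi_distance(s2, m)
  expect_false(bpi2$bonding)
  expect_gt(bpi2$distance, 3.6)

  # no phosphate present: NA
  out3 <- build_ideal_site(site_blueprint())
  s3 <- find_nucleotide_sites(out3$model)[[1]]
  expect_true(is.na(beta_pi_distance(s3, out3$model)$distance))
})

test_that("measured distances are invariant under rigid motion", {
  out <- build_ideal_site(site_blueprint(gamma_moiety = "ALF4"))
  m <- out$model
  s <- find_nucleotide_sites(m)[[1]]
  ann <- annotate_site(s, m)
  m2 <- rotate_model(m)
  s2 <- find_nucleotide_sites(m2)[[1]]
  ann2 <- annotate_site(s2, m2)
  expect_equal(wb_k1_distance(ann2), wb_k1_distance(ann), tolerance = 1e-6)
  expect_equal(hnk3_gamma_distance(ann2, s2), hnk3_gamma_distance(ann, s),
               tolerance = 1e-6)
  expect_equal(sort(ann2$shell$edges), sort(ann$shell$edges), tolerance = 1e-6)
})
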