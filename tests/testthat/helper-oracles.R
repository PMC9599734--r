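# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Monte-Carlo SASA: uniform random points on each expanded sphere
mc_sasa <- function(atoms, probe = 1.4, n = 5e4, seed = 1) {
  set.seed(seed)
  radii <- ploopscan::vdw_radii()
  r <- unname(radii[toupper(atoms$elesy)]) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  vapply(seq_len(nrow(xyz)), function(i) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * r[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n)
    for (j in seq_len(nrow(xyz))[-i]) {
      d2 <- colSums((t(p) - xyz[j, ])^2)
      exposed <- exposed & d2 > r[j]^2
    }
    mean(exposed) * 4 * pi * r[i]^2
  }, numeric(1))
}

# exact area of a sphere of radius r1 partially eaten by a sphere of radius
# r2 at centre distance d (spherical-cap formula)
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# permutation test on the difference of group means
perm_test <- function(x, y, n_perm = 2000, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  nx <- length(x)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), nx)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# brute-force Walker B rule re-implemented from scratch on the raw atom table
brute_walker_b <- function(model, k1_chain, k1_resno, cutoff = 5,
                           ionizable = c("GLU", "ASP", "SER", "THR", "TYR",
                                         "LYS", "ARG", "HIS")) {
  a <- model$atoms
  prot <- a[!a$het & a$chain == k1_chain, , drop = FALSE]
  hyd <- prot[prot$resno == k1_resno & prot$elety %in% c("OG", "OG1"), ,
              drop = FALSE]
  if (nrow(hyd) == 0L) return(NULL)
  p <- as.numeric(hyd[1, c("x", "y", "z")])
  resl <- unique(prot[order(prot$resno), c("resno", "resid")])
  cands <- NULL
  for (i in which(resl$resid %in% c("ASP", "GLU"))) {
    if (resl$resno[i] == k1_resno) next
    co <- prot[prot$resno == resl$resno[i] &
                 prot$elety %in% c("OD1", "OD2", "OE1", "OE2"), , drop = FALSE]
    if (nrow(co) == 0L) next
    d <- min(sqrt((co$x - p[1])^2 + (co$y - p[2])^2 + (co$z - p[3])^2))
    if (d <= cutoff) {
      j <- match(resl$resno[i] - 1:3, resl$resno)
      ok <- !any(is.na(j)) && !any(resl$resid[j] %in% ionizable)
      cands <- rbind(cands, data.frame(resno = resl$resno[i], d = d, ok = ok))
    }
  }
  if (is.null(cands)) return(NULL)
  cands <- cands[order(cands$d), , drop = FALSE]
  if (any(cands$ok)) {
    list(resno = cands$resno[which(cands$ok)[1]], fallback = FALSE)
  } else {
    list(resno = cands$resno[1], fallback = TRUE)
  }
}

# rigid motion helper
rotate_model <- function(model, angle = 0.9, axis = c(1, 2, 2),
                         shift = c(4, -7, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model
}

# minimal mmCIF writer for fixtures (atom_site loop with auth fields)
write_minimal_cif <- function(model, path) {
  at <- model$atoms
  hdr <- c("data_FIXTURE",
           if (is.finite(model$resolution %||% NA))
             sprintf("_refine.ls_d_res_high %.2f", model$resolution),
           "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
                  ifelse(at$het, "HETATM", "ATOM"), seq_len(nrow(at)),
                  at$elesy, at$elety, at$resid, at$chain, at$resno,
                  at$x, at$y, at$z, at$o, at$resno, at$resid, at$chain,
                  at$elety)
  writeLines(c(hdr, rows), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
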