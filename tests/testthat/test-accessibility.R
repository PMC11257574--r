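test_that("isolated-atom SASA matches the closed-form sphere area", {
  m <- one_atom_model(rbind(c(0, 0, 0)))
  s <- compute_sasa(m)
  expect_equal(s$residues$sasa, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  # nitrogen radius
  mn <- one_atom_model(rbind(c(0, 0, 0)), element = "N")
  expect_equal(compute_sasa(mn)$residues$sasa, 4 * pi * (1.55 + 1.4)^2,
               tolerance = 0.02)
})

test_that("coincident spheres count one surface; caps follow the closed form", {
  m2 <- one_atom_model(rbind(c(0, 0, 0), c(0, 0, 0)))
  s2 <- compute_sasa(m2)
  one <- 4 * pi * 3.1^2
  expect_equal(sum(s2$residues$sasa), one, tolerance = 0.02)

  for (d in c(1.0, 2.0, 4.0)) {
    mp <- one_atom_model(rbind(c(0, 0, 0), c(d, 0, 0)))
    sp <- compute_sasa(mp)
    want <- one * cap_exposed_fraction(d, 3.1)
    expect_equal(sp$residues$sasa[1], want, tolerance = 0.01)
  }
})

test_that("a caged atom is effectively buried", {
  cage <- septexo:::sphere_points(80) * 3.2
  coords <- rbind(c(0, 0, 0), cage)
  m <- one_atom_model(coords,
                      chains = c("A", rep("Z", nrow(cage))))
  # all cage atoms share residue numbers 2..n on chain Z; fine for SASA
  s <- compute_sasa(m)
  centre <- s$residues$sasa[s$residues$chain == "A"]
  expect_lt(centre, 0.01 * 4 * pi * 3.1^2)
})

test_that("SASA is rigid-transform invariant and monotone under added atoms", {
  pm <- make_pair_model(n_res_a = 6, n_res_b = 6, n_planted_contacts = 3,
                        seed = 8)
  s0 <- compute_sasa(pm$model)
  rot <- function(xyz) {
    th <- 0.7; ph <- 0.3
    rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
    sweep(xyz %*% rz %*% rx, 2L, c(5, -3, 11), "+")
  }
  moved <- pm$model
  moved$atoms[, c("x", "y", "z")] <-
    rot(as.matrix(pm$model$atoms[, c("x", "y", "z")]))
  s1 <- compute_sasa(moved)
  expect_equal(s1$residues$sasa, s0$residues$sasa, tolerance = 0.01)

  # adding a chain of atoms never increases an existing residue's SASA
  extra <- make_pair_model(n_res_a = 6, n_res_b = 6, n_planted_contacts = 0,
                           chain_pair = c("C", "D"), seed = 9)
  grown <- structure_model(rbind(pm$model$atoms[, 1:10],
                                 extra$model$atoms[, 1:10]),
                           model_id = "grown")
  s2 <- compute_sasa(grown)
  joint <- merge(s0$residues, s2$residues, by = c("chain", "resno"))
  expect_true(all(joint$sasa.y <= joint$sasa.x + 1e-9))
})

test_that("relative SASA normalizes by the residue-type maximum", {
  expect_identical(relative_sasa(0, "ALA"), 0)
  expect_identical(relative_sasa(129.0, "ALA"), 1)
  expect_error(relative_sasa(10, "XXX"), "not in the max-ASA table")
  # planted partial exposure from the spherical-cap oracle
  m <- one_atom_model(rbind(c(0, 0, 0), c(2, 0, 0)))
  s <- compute_sasa(m)
  frac <- cap_exposed_fraction(2, 3.1)
  expect_equal(s$residues$sasa[1] / (4 * pi * 3.1^2), frac, tolerance = 0.01)
})

test_that("interface residues map through explicit offsets and trims", {
  cx <- make_complex_model(n_chains = 2, residues_per_chain = 6, seed = 2,
                           buried_fraction = 0)
  iface <- data.frame(subunit = cx$truth$chain, seq_index = cx$truth$resno,
                      resid = cx$truth$resid)
  offs <- list(A = list(chain = "A", offset = 0L),
               B = list(chain = "B", offset = 0L))
  m0 <- map_interface_residues(iface, cx$model, offs)
  expect_identical(nrow(m0$mapping), nrow(iface))
  expect_identical(nrow(m0$unmappable), 0L)

  # source numbered 101.., complex keeps 1..: offset -100 maps 150 -> 50
  src <- data.frame(subunit = "A", seq_index = cx$truth$resno[3] + 100L,
                    resid = cx$truth$resid[3])
  m1 <- map_interface_residues(
    src, cx$model,
    list(A = list(chain = "A", offset = -100L,
                  keep = list(c(101L, 110L)))))
  expect_identical(m1$mapping$target_index, cx$truth$resno[3])

  # a residue inside a trimmed range is reported, not dropped
  trimmed <- map_interface_residues(
    data.frame(subunit = "A", seq_index = 3L, resid = cx$truth$resid[3]),
    cx$model, list(A = list(chain = "A", offset = 0L,
                            keep = list(c(4L, 6L)))))
  expect_identical(nrow(trimmed$mapping), 0L)
  expect_match(trimmed$unmappable$reason, "trimmed")

  # off-by-one numbering shows up as a hard name mismatch
  wrong <- data.frame(subunit = "A", seq_index = 1L, resid = "ZZZ")
  expect_error(map_interface_residues(wrong, cx$model,
                                      list(A = list(chain = "A", offset = 0L))),
               "name mismatch")

  # collisions are rejected
  dup <- rbind(src, src)
  expect_error(map_interface_residues(
    dup, cx$model, list(A = list(chain = "A", offset = -100L))),
    "collision")
})

test_that("feasibility percent reflects planted exposure labels exactly", {
  run_feas <- function(cx, thr = 0.25) {
    sasa <- compute_sasa(cx$model)
    iface <- data.frame(subunit = cx$truth$chain, seq_index = cx$truth$resno,
                        resid = cx$truth$resid)
    offs <- lapply(unique(cx$truth$chain),
                   function(ch) list(chain = ch, offset = 0L))
    names(offs) <- unique(cx$truth$chain)
    feasibility_percent(map_interface_residues(iface, cx$model, offs), sasa,
                        rsa_threshold = thr)
  }
  all_exposed <- make_complex_model(buried_fraction = 0, seed = 5,
                                    n_chains = 2, residues_per_chain = 8)
  expect_identical(run_feas(all_exposed)$percent_accessible, 100)

  half <- make_complex_model(n_chains = 4, residues_per_chain = 10,
                             buried_fraction = 0.5, seed = 6)
  rep_half <- run_feas(half)
  expect_equal(rep_half$percent_accessible, 100 * mean(half$truth$exposed))

  # monotone non-increasing in the threshold; threshold 0 gives 100%
  expect_identical(run_feas(half, 0)$percent_accessible, 100)
  p <- vapply(c(0.05, 0.25, 0.6, 1.0),
              function(t) run_feas(half, t)$percent_accessible, numeric(1))
  expect_true(all(diff(p) <= 0))

  sasa <- compute_sasa(half$model)
  empty <- data.frame(subunit = character(), seq_index = integer(),
                      resid = character(), chain = character(),
                      target_index = integer())
  expect_error(feasibility_percent(empty, sasa), "undefined")
})
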