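test_that("separated chains yield no contacts and planted interfaces exactly k", {
  none <- make_pair_model(n_res_a = 10, n_res_b = 10, n_planted_contacts = 0,
                          seed = 3)
  expect_identical(nrow(extract_contacts(none$model, c("A", "B"))), 0L)

  for (seed in c(1, 5, 9)) {
    k <- 4 + seed %% 3
    pm <- make_pair_model(n_res_a = 25, n_res_b = 25, n_planted_contacts = k,
                          seed = seed)
    got <- extract_contacts(pm$model, c("A", "B"))
    expect_identical(nrow(got), as.integer(k))
    planted <- pm$truth$planted[order(pm$truth$planted$res_a), ]
    expect_identical(got$res_a_index, planted$res_a)
    expect_identical(got$res_b_index, planted$res_b)
    expect_equal(got$min_distance, planted$distance, tolerance = 5e-3)
  }
})

test_that("the 4 A cutoff is inclusive", {
  m <- one_atom_model(rbind(c(0, 0, 0), c(4, 0, 0)),
                      chains = c("A", "B"))
  ct <- extract_contacts(m, c("A", "B"), cutoff_angstrom = 4.0)
  expect_identical(nrow(ct), 1L)
  expect_identical(ct$min_distance, 4.0)
  just_out <- one_atom_model(rbind(c(0, 0, 0), c(4.001, 0, 0)),
                             chains = c("A", "B"))
  expect_identical(nrow(extract_contacts(just_out, c("A", "B"))), 0L)
})

test_that("contact extraction matches the brute-force oracle and is symmetric", {
  for (seed in 1:8) {
    set.seed(seed)
    pm <- make_pair_model(n_res_a = sample(5:30, 1), n_res_b = sample(5:30, 1),
                          n_planted_contacts = sample(0:5, 1), seed = seed)
    expect_contacts_equal_oracle(pm$model, c("A", "B"))
    ab <- extract_contacts(pm$model, c("A", "B"))
    ba <- extract_contacts(pm$model, c("B", "A"))
    ba_flip <- ba[order(ba$res_b_index, ba$res_a_index), ]
    expect_equal(ab$res_a_index, ba_flip$res_b_index)
    expect_equal(ab$res_b_index, ba_flip$res_a_index)
    expect_equal(ab$min_distance, ba_flip$min_distance, tolerance = 1e-6)
  }
})

test_that("contact sets grow monotonically with the cutoff", {
  key <- function(ct) paste(ct$res_a_index, ct$res_b_index)
  for (seed in 1:10) {
    pm <- make_pair_model(n_res_a = 15, n_res_b = 15, n_planted_contacts = 4,
                          seed = seed)
    c35 <- extract_contacts(pm$model, c("A", "B"), 3.5)
    c40 <- extract_contacts(pm$model, c("A", "B"), 4.0)
    c50 <- extract_contacts(pm$model, c("A", "B"), 5.0)
    expect_true(all(key(c35) %in% key(c40)))
    expect_true(all(key(c40) %in% key(c50)))
  }
})

test_that("confidence filtering excludes below-50 partners and keeps exactly 50", {
  pl_a <- c(90, 49.99, 50, 75, 90)
  pl_b <- c(90, 90, 90, 90, 90)
  pm <- make_pair_model(n_res_a = 5, n_res_b = 5, n_planted_contacts = 5,
                        plddt_a = pl_a, plddt_b = pl_b, seed = 11)
  ct <- extract_contacts(pm$model, c("A", "B"))
  kept <- filter_by_plddt(ct, pm$model, min_plddt = 50)
  expect_false(2L %in% kept$res_a_index)   # 49.99 side excluded
  expect_true(3L %in% kept$res_a_index)    # exactly 50 retained
  expect_identical(nrow(kept), 4L)
})

test_that("filtering agrees with an independent per-residue scan and contracts", {
  for (seed in c(2, 6)) {
    pm <- make_pair_model(n_res_a = 20, n_res_b = 20, n_planted_contacts = 8,
                          seed = seed)
    ct <- extract_contacts(pm$model, c("A", "B"))
    kept <- filter_by_plddt(ct, pm$model, 50)
    want <- ct[pm$truth$plddt_a[as.character(ct$res_a_index)] >= 50 &
                 pm$truth$plddt_b[as.character(ct$res_b_index)] >= 50, ]
    expect_equal(kept$res_a_index, want$res_a_index)
    expect_lte(nrow(kept), nrow(ct))
    for (thr in c(0, 30, 60, 90)) {
      expect_lte(nrow(filter_by_plddt(ct, pm$model, thr + 10)),
                 nrow(filter_by_plddt(ct, pm$model, thr)))
    }
    either <- filter_by_plddt(ct, pm$model, 50, scope = "either")
    expect_gte(nrow(either), nrow(kept))
  }
})

test_that("model ranking is descending, permutation-invariant and id-tie-broken", {
  mk <- function(v, id) {
    make_pair_model(n_res_a = 4, n_res_b = 4, n_planted_contacts = 0,
                    plddt_a = rep(v, 4), plddt_b = rep(v, 4),
                    model_id = id, seed = 1)$model
  }
  models <- list(mk(70, "m3"), mk(90, "m1"), mk(50, "m5"),
                 mk(80, "m2"), mk(60, "m4"))
  ranked <- rank_models(models)
  expect_identical(vapply(ranked, function(m) m$model_id, ""),
                   paste0("m", 1:5))
  expect_identical(vapply(ranked, function(m) m$rank, 1L), 1:5)
  shuffled <- rank_models(models[c(4, 1, 5, 2, 3)])
  expect_identical(vapply(shuffled, function(m) m$model_id, ""),
                   vapply(ranked, function(m) m$model_id, ""))
  tied <- rank_models(list(mk(80, "zzz"), mk(80, "aaa")))
  expect_identical(tied[[1]]$model_id, "aaa")
})

test_that("consensus needs filtered contacts in both input orders", {
  with_iface <- make_pair_model(n_planted_contacts = 10, seed = 21,
                                plddt_a = rep(90, 30), plddt_b = rep(90, 30))
  without <- make_pair_model(n_planted_contacts = 0, seed = 22,
                             plddt_a = rep(90, 30), plddt_b = rep(90, 30))
  with_iface$model$rank <- without$model$rank <- 1L
  i_ab <- interface_set(with_iface$model, c("A", "B"), "X:Y", "A:B")
  i_ba_empty <- interface_set(without$model, c("A", "B"), "X:Y", "B:A")
  one_sided <- evaluate_pair(i_ab, i_ba_empty)
  expect_false(one_sided$consensus)
  expect_identical(one_sided$score, 0)

  both <- evaluate_pair(i_ab, i_ab)
  expect_true(both$consensus)
  # score equals an independent mean over the planted confidences
  res <- unique(c(i_ab$filtered_contacts$res_a_index))
  resb <- unique(i_ab$filtered_contacts$res_b_index)
  want <- mean(c(with_iface$truth$plddt_a[as.character(res)],
                 with_iface$truth$plddt_b[as.character(resb)]))
  expect_equal(both$score, want)
  expect_error(evaluate_pair(i_ab, interface_set(without$model, c("A", "B"),
                                                 "OTHER:PAIR", "B:A")),
               "different pairs")
})

test_that("the grid screen recovers exactly the planted consensus pairs", {
  grid <- make_screen_grid(n_consensus = 3, n_one_sided = 2, n_low_conf = 1,
                           n_models = 2, n_res = 6, seed = 17)
  scr <- screen_all_pairs(grid$model_table)
  found <- sort(scr$table$pair[scr$table$consensus])
  expect_identical(found, grid$truth$consensus_pairs)
  # consensus block first, descending score
  expect_identical(scr$table$consensus,
                   sort(scr$table$consensus, decreasing = TRUE))
  sc <- scr$table$score[scr$table$consensus]
  expect_identical(sc, sort(sc, decreasing = TRUE))
  # low-confidence decoys found an interface but fail the filter
  lc <- scr$table[scr$table$pair %in% grid$truth$low_conf_pairs, ]
  expect_true(all(lc$n_contacts_ab > 0 & lc$n_filtered_ab == 0))
})

test_that("a missing input order is a warning, not a failure", {
  grid <- make_screen_grid(n_consensus = 1, n_one_sided = 0, n_low_conf = 0,
                           n_models = 1, n_res = 5, seed = 5)
  tab <- grid$model_table[-1]
  scr <- screen_all_pairs(tab)
  expect_length(scr$warnings, 1L)
  expect_identical(nrow(scr$table), 31L)
  # duplicated orders are idempotent
  dup <- c(grid$model_table, grid$model_table[1])
  scr2 <- screen_all_pairs(dup)
  scr1 <- screen_all_pairs(grid$model_table)
  expect_identical(scr1$table, scr2$table)
})
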