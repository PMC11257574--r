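# Independent oracles used across the suite. These deliberately take
# the slow, direct route (explicit loops over residue pairs, plain
# re-summation) so they share no code path with the implementation.

# Brute-force all-atom-pairs contact oracle: for every inter-chain
# residue pair, the minimum heavy-atom distance via explicit outer
# differences.
oracle_contacts <- function(model, chain_pair, cutoff = 4.0) {
  a <- model$atoms[model$atoms$chain == chain_pair[1] & !model$atoms$is_h, ]
  b <- model$atoms[model$atoms$chain == chain_pair[2] & !model$atoms$is_h, ]
  rows <- list()
  for (ra in unique(a$resno)) {
    pa <- a[a$resno == ra, ]
    for (rb in unique(b$resno)) {
      pb <- b[b$resno == rb, ]
      d <- sqrt(outer(pa$x, pb$x, "-")^2 + outer(pa$y, pb$y, "-")^2 +
                  outer(pa$z, pb$z, "-")^2)
      if (min(d) <= cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          res_a_index = ra, res_b_index = rb, min_distance = min(d))
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(res_a_index = integer(), res_b_index = integer(),
                      min_distance = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$res_a_index, out$res_b_index), , drop = FALSE]
}

expect_contacts_equal_oracle <- function(model, chain_pair, cutoff = 4.0) {
  got <- extract_contacts(model, chain_pair, cutoff)
  want <- oracle_contacts(model, chain_pair, cutoff)
  expect_equal(got$res_a_index, want$res_a_index)
  expect_equal(got$res_b_index, want$res_b_index)
  expect_equal(got$min_distance, want$min_distance, tolerance = 1e-6)
}

# Single-atom structure_model helper.
one_atom_model <- function(coords, plddt = 90, resid = "ALA",
                           element = "C", chains = NULL) {
  n <- nrow(coords)
  if (is.null(chains)) chains <- rep("A", n)
  structure_model(data.frame(
    chain = chains, resno = seq_len(n), resid = resid,
    eleno = seq_len(n), elety = "CA", element = element,
    x = coords[, 1], y = coords[, 2], z = coords[, 3], plddt = plddt
  ), model_id = "fixture")
}

# Spherical-cap closed form: exposed fraction of a sphere of extended
# radius `ext` occluded by one identical sphere at centre distance d.
cap_exposed_fraction <- function(d, ext) {
  if (d >= 2 * ext) return(1)
  1 - (ext - d / 2) / (2 * ext)
}

expect_models_equal <- function(m1, m2) {
  a <- m1$atoms; b <- m2$atoms
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$chain, b$chain)
  expect_equal(a$resno, b$resno)
  expect_equal(a$resid, b$resid)
  expect_equal(a$elety, b$elety)
  expect_equal(round(a$x, 3), round(b$x, 3))
  expect_equal(round(a$y, 3), round(b$y, 3))
  expect_equal(round(a$z, 3), round(b$z, 3))
  expect_equal(round(a$plddt, 2), round(b$plddt, 2))
}
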