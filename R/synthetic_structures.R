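# Standard 20 residue codes used to label synthetic residues.
.aa3 <- names(.max_asa_theoretical)

# Five-heavy-atom residue template (poly-alanine-like: N, CA, C, O, CB).
# All offsets have dy <= 0 so that the CA sits closest to anything
# approaching from +y; the generator exploits this to plant exact
# minimum inter-chain distances on the CA-CA axis.
.res_template <- matrix(
  c(-0.5, -0.4,  0.2,   # N
     0.0,  0.0,  0.0,   # CA
     0.5, -0.3, -0.2,   # C
     0.6, -1.0,  0.3,   # O
    -0.3, -1.2, -0.4),  # CB
  ncol = 3, byrow = TRUE,
  dimnames = list(c("N", "CA", "C", "O", "CB"), NULL)
)
.template_elements <- c("N", "C", "C", "O", "C")

# Build an atom block for one residue at a given centre; flip = TRUE
# mirrors the template in y (offsets >= 0), used for the second chain.
residue_atoms <- function(centre, chain, resno, resid, eleno0, plddt,
                          flip = FALSE) {
  off <- .res_template
  if (flip) off[, 2] <- -off[, 2]
  data.frame(
    chain = chain, resno = resno, resid = resid,
    eleno = eleno0 + seq_len(nrow(off)) - 1L,
    elety = rownames(.res_template), element = .template_elements,
    x = round(centre[1] + off[, 1], 3),
    y = round(centre[2] + off[, 2], 3),
    z = round(centre[3] + off[, 3], 3),
    plddt = plddt, stringsAsFactors = FALSE
  )
}

#' Synthetic two-chain model with planted interface contacts
#'
#' Builds a two-chain poly-alanine-like model on a non-clashing
#' scaffold: chain A residues sit on a line at 8 A spacing, chain B
#' residues on a parallel line 25 A away. Exactly `n_planted_contacts`
#' chain-B residues are relocated so their CA lies at a drawn distance
#' (within `contact_distance_range`) from the CA of a distinct chain-A
#' partner residue; every other inter-chain residue pair stays > 6 A
#' (guard margin). Coordinates are rounded to 3 decimals (the file
#' precision), so realized minimum distances match the planted ones to
#' ~2e-3 A.
#'
#' @param n_res_a,n_res_b residues per chain.
#' @param n_planted_contacts number of planted contact pairs
#'   (<= min(n_res_a, n_res_b)).
#' @param contact_distance_range length-2 numeric inside (2.5, 4];
#'   planted CA-CA distances are drawn uniformly from it.
#' @param plddt_a,plddt_b per-residue confidence vectors (default:
#'   uniform on [40, 95], rounded to 2 decimals).
#' @param chain_pair chain ids (default A, B).
#' @param resno_start first residue number of each chain.
#' @param subunits optional named subunit labels.
#' @param model_id model identifier.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return list with `model` (a [structure_model()]) and `truth`
#'   (planted contact table, pLDDT vectors, parameters, seed).
#' @export
make_pair_model <- function(n_res_a = 30L, n_res_b = 30L,
                            n_planted_contacts = 6L,
                            contact_distance_range = c(3.0, 3.9),
                            plddt_a = NULL, plddt_b = NULL,
                            chain_pair = c("A", "B"),
                            resno_start = c(1L, 1L),
                            subunits = NULL, model_id = "synthetic_pair",
                            seed = 1L) {
  if (n_planted_contacts > min(n_res_a, n_res_b)) {
    stop("infeasible geometry: more planted contacts than residues per chain")
  }
  if (contact_distance_range[1] <= 2.5 || contact_distance_range[2] > 4.0 ||
      diff(contact_distance_range) < 0) {
    stop("contact_distance_range must lie inside (2.5, 4]")
  }
  if (!is.null(seed)) set.seed(seed)
  spacing <- 8
  if (is.null(plddt_a)) plddt_a <- round(stats::runif(n_res_a, 40, 95), 2)
  if (is.null(plddt_b)) plddt_b <- round(stats::runif(n_res_b, 40, 95), 2)
  resid_a <- sample(.aa3, n_res_a, replace = TRUE)
  resid_b <- sample(.aa3, n_res_b, replace = TRUE)
  resno_a <- resno_start[1] + seq_len(n_res_a) - 1L
  resno_b <- resno_start[2] + seq_len(n_res_b) - 1L

  ia <- sort(sample.int(n_res_a, n_planted_contacts))
  ib <- sample.int(n_res_b, n_planted_contacts)
  dists <- round(stats::runif(n_planted_contacts,
                              contact_distance_range[1],
                              contact_distance_range[2]), 3)

  blocks <- vector("list", n_res_a + n_res_b)
  eleno <- 1L
  for (i in seq_len(n_res_a)) {
    blocks[[i]] <- residue_atoms(c(spacing * i, 0, 0), chain_pair[1],
                                 resno_a[i], resid_a[i], eleno, plddt_a[i])
    eleno <- eleno + 5L
  }
  for (j in seq_len(n_res_b)) {
    hit <- match(j, ib)
    centre <- if (!is.na(hit)) {
      c(spacing * ia[hit], dists[hit], 0)
    } else {
      c(spacing * j + 4, 25, 0)
    }
    blocks[[n_res_a + j]] <- residue_atoms(centre, chain_pair[2],
                                           resno_b[j], resid_b[j], eleno,
                                           plddt_b[j], flip = TRUE)
    eleno <- eleno + 5L
  }
  model <- structure_model(do.call(rbind, blocks), model_id = model_id,
                           subunits = subunits)
  truth <- list(
    planted = data.frame(res_a = resno_a[ia], res_b = resno_b[ib],
                         distance = dists),
    plddt_a = stats::setNames(plddt_a, resno_a),
    plddt_b = stats::setNames(plddt_b, resno_b),
    params = list(n_res_a = n_res_a, n_res_b = n_res_b,
                  n_planted_contacts = n_planted_contacts,
                  contact_distance_range = contact_distance_range),
    seed = seed
  )
  list(model = model, truth = truth)
}

#' Synthetic all-vs-all screen dataset
#'
#' Emulates the paper-scale design: a 4 x 8 grid of septin and exocyst
#' subunits, every pair predicted in both input orders with
#' `n_models` sampled models each. A chosen number of pairs carry
#' genuine bidirectional interfaces (high-confidence contacts in the
#' rank-1 model of both orders); decoys carry either a one-sided
#' interface (contacts in a single order) or a low-confidence
#' bidirectional interface (all contact residues below the pLDDT
#' filter). Remaining pairs have separated chains.
#'
#' @param septins,exocyst subunit name vectors (defaults: Spn1-4 and
#'   the eight exocyst subunits).
#' @param n_consensus planted bidirectional interactions (default 6).
#' @param n_one_sided one-sided decoy pairs (default 4).
#' @param n_low_conf low-confidence bidirectional decoys (default 2).
#' @param n_models models per ordered pair (default 5).
#' @param n_res residues per chain (default 8).
#' @param n_contacts planted contacts per interface (default 4).
#' @param seed RNG seed.
#' @return list with `model_table` (named list `"X|Y"` -> list of
#'   models, ready for [screen_all_pairs()]) and `truth` (consensus /
#'   decoy pair labels).
#' @export
make_screen_grid <- function(septins = paste0("Spn", 1:4),
                             exocyst = c("Sec3", "Sec5", "Sec6", "Sec8",
                                         "Sec10", "Sec15", "Exo70", "Exo84"),
                             n_consensus = 6L, n_one_sided = 4L,
                             n_low_conf = 2L, n_models = 5L, n_res = 8L,
                             n_contacts = 4L, seed = 1L) {
  set.seed(seed)
  pairs <- expand.grid(septin = septins, exocyst = exocyst,
                       stringsAsFactors = FALSE)
  n_pairs <- nrow(pairs)
  if (n_consensus + n_one_sided + n_low_conf > n_pairs) {
    stop("more planted/decoy pairs than grid cells")
  }
  roles <- rep("empty", n_pairs)
  picked <- sample.int(n_pairs, n_consensus + n_one_sided + n_low_conf)
  roles[picked] <- rep(c("consensus", "one_sided", "low_conf"),
                       c(n_consensus, n_one_sided, n_low_conf))

  model_table <- list()
  for (i in seq_len(n_pairs)) {
    s <- pairs$septin[i]; e <- pairs$exocyst[i]
    role <- roles[i]
    for (ord in 1:2) {
      first <- if (ord == 1) s else e
      second <- if (ord == 1) e else s
      key <- paste(first, second, sep = "|")
      has_iface <- switch(role,
        consensus = TRUE,
        low_conf = TRUE,
        one_sided = ord == 1,
        empty = FALSE)
      base_conf <- if (role == "low_conf") c(30, 45) else c(75, 95)
      models <- vector("list", n_models)
      for (m in seq_len(n_models)) {
        # model 1 is built to rank first (highest confidence band);
        # lower models carry no interface
        lo <- max(base_conf[1] - 10 * (m - 1), 5)
        hi <- max(base_conf[2] - 10 * (m - 1), 15)
        pl_a <- round(stats::runif(n_res, lo, hi), 2)
        pl_b <- round(stats::runif(n_res, lo, hi), 2)
        models[[m]] <- make_pair_model(
          n_res_a = n_res, n_res_b = n_res,
          n_planted_contacts = if (m == 1L && has_iface) n_contacts else 0L,
          plddt_a = pl_a, plddt_b = pl_b,
          subunits = stats::setNames(c(first, second), c("A", "B")),
          model_id = paste0(key, "_model", m),
          seed = NULL
        )$model
      }
      model_table[[key]] <- models
    }
  }
  label <- function(idx) {
    vapply(idx, function(i) paste(sort(c(pairs$septin[i], pairs$exocyst[i])),
                                  collapse = ":"), character(1))
  }
  list(model_table = model_table,
       truth = list(consensus_pairs = sort(label(which(roles == "consensus"))),
                    one_sided_pairs = sort(label(which(roles == "one_sided"))),
                    low_conf_pairs = sort(label(which(roles == "low_conf"))),
                    seed = seed))
}

# Deterministic well-separated 3-D site positions: cubic grid, 14 A
# spacing, filled in a fixed order.
site_positions <- function(n, spacing = 14) {
  side <- ceiling(n^(1 / 3))
  g <- expand.grid(ix = seq_len(side), iy = seq_len(side), iz = seq_len(side))
  as.matrix(g[seq_len(n), ]) * spacing
}

#' Synthetic assembled complex with known buried/exposed residues
#'
#' Builds a multi-chain model in which every residue is a compact
#' five-atom cluster on a well-separated spatial grid. Residues
#' labelled buried are enclosed by an 80-atom spherical cage (a
#' scaffold chain "Z"), forcing their relative SASA near zero; exposed
#' residues sit in open space. The labels are the ground truth for
#' feasibility classification.
#'
#' @param n_chains real chains (default 4).
#' @param residues_per_chain residues per real chain (default 10).
#' @param buried_fraction fraction of real residues caged (default
#'   0.3).
#' @param seed RNG seed.
#' @param validate if TRUE, run [compute_sasa()] on the result and
#'   assert buried relative SASA < 0.05 and exposed > 0.5.
#' @return list with `model`, `truth` (data.frame `chain`, `resno`,
#'   `resid`, `exposed`) and, when validated, `validation`.
#' @export
make_complex_model <- function(n_chains = 4L, residues_per_chain = 10L,
                               buried_fraction = 0.3, seed = 1L,
                               validate = FALSE) {
  set.seed(seed)
  n_res <- n_chains * residues_per_chain
  n_buried <- round(buried_fraction * n_res)
  buried_idx <- sort(sample.int(n_res, n_buried))
  sites <- site_positions(n_res)
  chains <- LETTERS[seq_len(n_chains)]
  resid <- sample(.aa3, n_res, replace = TRUE)

  blocks <- list(); eleno <- 1L
  for (i in seq_len(n_res)) {
    ch <- chains[(i - 1L) %/% residues_per_chain + 1L]
    rn <- (i - 1L) %% residues_per_chain + 1L
    blocks[[length(blocks) + 1L]] <-
      residue_atoms(sites[i, ], ch, rn, resid[i], eleno, 90)
    eleno <- eleno + 5L
  }
  cage_dirs <- sphere_points(80L)
  for (k in seq_along(buried_idx)) {
    centre <- sites[buried_idx[k], ]
    pts <- sweep(cage_dirs * 3.2, 2L, centre, "+")
    blocks[[length(blocks) + 1L]] <- data.frame(
      chain = "Z", resno = k, resid = "UNK",
      eleno = eleno + seq_len(nrow(pts)) - 1L,
      elety = "C", element = "C",
      x = round(pts[, 1], 3), y = round(pts[, 2], 3), z = round(pts[, 3], 3),
      plddt = 90, stringsAsFactors = FALSE
    )
    eleno <- eleno + nrow(pts)
  }
  model <- structure_model(do.call(rbind, blocks),
                           model_id = "synthetic_complex")
  truth <- data.frame(
    chain = rep(chains, each = residues_per_chain),
    resno = rep(seq_len(residues_per_chain), n_chains),
    resid = resid,
    exposed = !(seq_len(n_res) %in% buried_idx),
    stringsAsFactors = FALSE
  )
  out <- list(model = model, truth = truth)
  if (validate) {
    sr <- compute_sasa(model)
    res <- sr$residues[sr$residues$chain != "Z", ]
    rel <- res$rel_sasa[match(paste(truth$chain, truth$resno),
                              paste(res$chain, res$resno))]
    ok <- all(rel[!truth$exposed] < 0.05) && all(rel[truth$exposed] > 0.5)
    if (!ok) stop("construction-time SASA check failed")
    out$validation <- list(rel_sasa = rel, passed = ok)
  }
  out
}
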