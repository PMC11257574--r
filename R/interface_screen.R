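#' Extract inter-chain contact residues
#'
#' Interface residues are defined as residue pairs of two chains having
#' any non-hydrogen atom pair within `cutoff_angstrom` (inclusive), the
#' standard heavy-atom contact convention at a 4 A scale. Each residue
#' pair is reported once with its minimum heavy-atom distance.
#'
#' @param model a [structure_model()] containing both chains.
#' @param chain_pair character vector of two distinct chain ids; the
#'   first is reported as side "a".
#' @param cutoff_angstrom positive distance cutoff in Angstrom
#'   (default 4.0).
#' @return data.frame with columns `chain_a`, `res_a_index`,
#'   `res_a_name`, `chain_b`, `res_b_index`, `res_b_name`,
#'   `min_distance`, ordered by `res_a_index` then `res_b_index`.
#' @export
extract_contacts <- function(model, chain_pair, cutoff_angstrom = 4.0) {
  if (length(chain_pair) != 2L || chain_pair[1] == chain_pair[2]) {
    stop("chain_pair must name two distinct chains")
  }
  if (!is.numeric(cutoff_angstrom) || cutoff_angstrom <= 0) {
    stop("cutoff_angstrom must be > 0")
  }
  aa <- chain_atoms(model, chain_pair[1])
  ab <- chain_atoms(model, chain_pair[2])
  if (nrow(aa) == 0L || nrow(ab) == 0L) {
    stop("both chains need at least one non-hydrogen atom")
  }
  pa <- as.matrix(aa[, c("x", "y", "z")])
  pb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  d2[d2 < 0] <- 0  # numerical noise on coincident atoms
  hits <- which(d2 <= cutoff_angstrom^2, arr.ind = TRUE)
  empty <- data.frame(chain_a = character(), res_a_index = integer(),
                      res_a_name = character(), chain_b = character(),
                      res_b_index = integer(), res_b_name = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  ra <- aa$resno[hits[, 1]]
  rb <- ab$resno[hits[, 2]]
  key <- paste(ra, rb, sep = "|")
  mind <- tapply(sqrt(d2[hits]), key, min)
  parts <- do.call(rbind, strsplit(names(mind), "|", fixed = TRUE))
  res_a <- as.integer(parts[, 1]); res_b <- as.integer(parts[, 2])
  name_a <- stats::setNames(aa$resid[!duplicated(aa$resno)],
                            aa$resno[!duplicated(aa$resno)])
  name_b <- stats::setNames(ab$resid[!duplicated(ab$resno)],
                            ab$resno[!duplicated(ab$resno)])
  out <- data.frame(
    chain_a = chain_pair[1], res_a_index = res_a,
    res_a_name = unname(name_a[as.character(res_a)]),
    chain_b = chain_pair[2], res_b_index = res_b,
    res_b_name = unname(name_b[as.character(res_b)]),
    min_distance = as.numeric(mind), stringsAsFactors = FALSE
  )
  out <- out[order(out$res_a_index, out$res_b_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter contacts by residue confidence
#'
#' Retains a contact only when its partner residues pass the pLDDT
#' threshold (residues with pLDDT below 50 are excluded by default,
#' i.e. a residue at exactly 50 is retained). By default both sides
#' must pass: a contact with one unreliable side is unreliable.
#'
#' @param contacts data.frame from [extract_contacts()].
#' @param model the [structure_model()] the contacts came from.
#' @param min_plddt retention threshold (default 50); a residue passes
#'   iff `plddt >= min_plddt`.
#' @param scope `"both"` (default) or `"either"`: how many partner
#'   residues must pass.
#' @return the retained subset of `contacts`, order preserved.
#' @export
filter_by_plddt <- function(contacts, model, min_plddt = 50,
                            scope = c("both", "either")) {
  scope <- match.arg(scope)
  if (nrow(contacts) == 0L) return(contacts)
  lk <- plddt_lookup(model)
  pa <- lk[paste(contacts$chain_a, contacts$res_a_index, sep = "|")]
  pb <- lk[paste(contacts$chain_b, contacts$res_b_index, sep = "|")]
  if (any(is.na(pa)) || any(is.na(pb))) {
    stop("contact references a residue missing from the model")
  }
  keep <- if (scope == "both") {
    pa >= min_plddt & pb >= min_plddt
  } else {
    pa >= min_plddt | pb >= min_plddt
  }
  out <- contacts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank predicted models by mean pLDDT
#'
#' Orders a set of models of the same prediction run descending by
#' model-mean pLDDT (ties broken by model_id, lexicographically) and
#' assigns ranks 1..n.
#'
#' @param models list of [structure_model()] objects.
#' @return the list reordered, each element with its `rank` field set.
#' @export
rank_models <- function(models) {
  if (length(models) == 0L) stop("need at least one model to rank")
  means <- vapply(models, mean_plddt, numeric(1))
  ids <- vapply(models, function(m) m$model_id, character(1))
  ord <- order(-means, ids)
  models <- models[ord]
  for (i in seq_along(models)) models[[i]]$rank <- i
  models
}

#' Build the interface of one ordered prediction
#'
#' Convenience wrapper binding [extract_contacts()] and
#' [filter_by_plddt()] on the rank-1 model of one input order into an
#' `interface_set` used by the consensus screen. The interface mean
#' pLDDT is the mean confidence over the unique residues taking part in
#' the filtered contacts.
#'
#' @param model rank-1 [structure_model()] of this input order.
#' @param chain_pair two chain ids, first chain = first-entered subunit.
#' @param pair_label unordered pair label (e.g. `"Sec15:Spn2"`).
#' @param order_tag which input order this model is (e.g. `"A:B"`).
#' @param cutoff_angstrom,min_plddt,scope passed through.
#' @return An `interface_set`: list with `pair_label`, `order_tag`,
#'   `model_rank`, `contacts`, `filtered_contacts`,
#'   `interface_mean_plddt` (NA when no filtered contact survives).
#' @export
interface_set <- function(model, chain_pair, pair_label, order_tag = "A:B",
                          cutoff_angstrom = 4.0, min_plddt = 50,
                          scope = "both") {
  contacts <- extract_contacts(model, chain_pair, cutoff_angstrom)
  filtered <- filter_by_plddt(contacts, model, min_plddt, scope)
  imp <- NA_real_
  if (nrow(filtered) > 0L) {
    lk <- plddt_lookup(model)
    keys <- unique(c(paste(filtered$chain_a, filtered$res_a_index, sep = "|"),
                     paste(filtered$chain_b, filtered$res_b_index, sep = "|")))
    imp <- mean(lk[keys])
  }
  structure(
    list(pair_label = pair_label, order_tag = order_tag,
         model_rank = model$rank, contacts = contacts,
         filtered_contacts = filtered, interface_mean_plddt = imp),
    class = "interface_set"
  )
}

#' Evaluate one subunit pair for bidirectional consensus
#'
#' A pair "shows an interaction" when at least `min_contacts`
#' confidence-filtered contacts survive in each of the two input orders
#' (the order of entered sequences affects predictions, so both orders
#' are required to agree). The ranking score is the minimum over the two
#' orders of the interface mean pLDDT (0 when undefined): a conservative
#' consensus confidence.
#'
#' @param interface_ab,interface_ba `interface_set` objects for the two
#'   input orders of the same unordered pair.
#' @param min_contacts minimum filtered contacts per order (default 1).
#' @return A `screen_result`: list with `pair_label`, `interface_ab`,
#'   `interface_ba`, `consensus` (logical), `score`.
#' @export
evaluate_pair <- function(interface_ab, interface_ba, min_contacts = 1L) {
  if (!identical(interface_ab$pair_label, interface_ba$pair_label)) {
    stop("interface sets refer to different pairs: ",
         interface_ab$pair_label, " vs ", interface_ba$pair_label)
  }
  if (min_contacts < 1L) stop("min_contacts must be >= 1")
  n_ab <- nrow(interface_ab$filtered_contacts)
  n_ba <- nrow(interface_ba$filtered_contacts)
  consensus <- n_ab >= min_contacts && n_ba >= min_contacts
  imps <- c(interface_ab$interface_mean_plddt, interface_ba$interface_mean_plddt)
  imps[is.na(imps)] <- 0
  structure(
    list(pair_label = interface_ab$pair_label,
         interface_ab = interface_ab, interface_ba = interface_ba,
         consensus = consensus, score = min(imps)),
    class = "screen_result"
  )
}

#' Screen all subunit pairs in both input orders
#'
#' Runs the bidirectional-order consensus over a table of pairwise
#' predictions. For each ordered pair the supplied models are ranked by
#' mean pLDDT and the rank-1 model defines the interface; a pair reaches
#' consensus when both input orders show at least `min_contacts`
#' filtered contacts.
#'
#' @param model_table named list: key `"X|Y"` (ordered: X entered
#'   first), value a list of [structure_model()] objects (typically the
#'   five sampled models) whose two chains are X then Y, in that chain
#'   order.
#' @param chain_map function mapping a model to its two chain ids in
#'   entry order; defaults to file chain order.
#' @param cutoff_angstrom,min_plddt,min_contacts,scope screen settings.
#' @return list with `results` (list of `screen_result`, consensus
#'   pairs first, then descending score), `table` (summary data.frame,
#'   one row per unordered pair) and `warnings` (character).
#' @export
screen_all_pairs <- function(model_table, cutoff_angstrom = 4.0,
                             min_plddt = 50, min_contacts = 1L,
                             scope = "both",
                             chain_map = function(m) chain_ids(m)[1:2]) {
  keys <- names(model_table)
  parts <- strsplit(keys, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("model_table keys must be 'X|Y'")
  ordered <- do.call(rbind, parts)
  unordered <- apply(ordered, 1L, function(p) paste(sort(p), collapse = ":"))
  warnings <- character()
  results <- list()
  for (pl in unique(unordered)) {
    subunits <- strsplit(pl, ":", fixed = TRUE)[[1]]
    k_ab <- keys[unordered == pl & ordered[, 1] == subunits[1]]
    k_ba <- keys[unordered == pl & ordered[, 1] == subunits[2]]
    if (length(k_ab) == 0L || length(k_ba) == 0L) {
      warnings <- c(warnings, paste0("pair ", pl,
                                     ": missing one input order; not evaluable"))
      next
    }
    make_iface <- function(key, tag) {
      top <- rank_models(model_table[[key]])[[1L]]
      iface <- interface_set(top, chain_map(top), pair_label = pl,
                             order_tag = tag,
                             cutoff_angstrom = cutoff_angstrom,
                             min_plddt = min_plddt, scope = scope)
      iface$model_mean_plddt <- mean_plddt(top)
      iface
    }
    results[[pl]] <- evaluate_pair(
      make_iface(k_ab[1L], "A:B"), make_iface(k_ba[1L], "B:A"),
      min_contacts = min_contacts
    )
  }
  ord <- order(!vapply(results, `[[`, logical(1), "consensus"),
               -vapply(results, `[[`, numeric(1), "score"),
               names(results))
  results <- results[ord]
  table <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      pair = r$pair_label,
      n_contacts_ab = nrow(r$interface_ab$contacts),
      n_filtered_ab = nrow(r$interface_ab$filtered_contacts),
      n_contacts_ba = nrow(r$interface_ba$contacts),
      n_filtered_ba = nrow(r$interface_ba$filtered_contacts),
      model_mean_plddt_ab = r$interface_ab$model_mean_plddt,
      model_mean_plddt_ba = r$interface_ba$model_mean_plddt,
      interface_mean_plddt_ab = r$interface_ab$interface_mean_plddt,
      interface_mean_plddt_ba = r$interface_ba$interface_mean_plddt,
      consensus = r$consensus, score = r$score,
      stringsAsFactors = FALSE
    )
  }))
  rownames(table) <- NULL
  list(results = results, table = table, warnings = warnings)
}
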