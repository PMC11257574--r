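#' Construct a structure model
#'
#' The shared container for predicted structure models: an atom table with
#' Angstrom coordinates and a per-residue confidence score (pLDDT, 0-100)
#' carried in the B-factor convention of predicted models.
#'
#' @param atoms data.frame with columns `chain` (character), `resno`
#'   (integer, author numbering, strictly increasing within a chain),
#'   `resid` (3-letter residue code), `eleno` (integer atom serial),
#'   `elety` (atom name, e.g. "CA"), `element` (element symbol), `x`,
#'   `y`, `z` (Angstrom) and `plddt` (0-100, identical for all atoms of a
#'   residue).
#' @param model_id character scalar identifying the model.
#' @param rank optional integer rank (1 = best) assigned by
#'   [rank_models()].
#' @param subunits optional named character vector mapping chain ids to
#'   biological subunit names (e.g. `c(A = "Spn1", B = "Sec3")`).
#'
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id, rank = NA_integer_, subunits = NULL) {
  required <- c("chain", "resno", "resid", "eleno", "elety", "element",
                "x", "y", "z", "plddt")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("a structure model needs at least one atom")
  atoms <- as.data.frame(atoms)[, required]
  atoms$chain <- as.character(atoms$chain)
  atoms$resid <- as.character(atoms$resid)
  atoms$elety <- as.character(atoms$elety)
  atoms$element <- as.character(atoms$element)
  atoms$resno <- as.integer(atoms$resno)
  atoms$eleno <- as.integer(atoms$eleno)

  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  if (any(is.na(atoms$element) | atoms$element == "")) {
    stop("every atom needs a non-empty element symbol")
  }
  if (any(!is.finite(atoms$plddt))) {
    stop("no confidence data: missing per-residue pLDDT values")
  }
  if (any(atoms$plddt < 0 | atoms$plddt > 100)) {
    stop("pLDDT values must lie in [0, 100]")
  }
  for (ch in unique(atoms$chain)) {
    rn <- atoms$resno[atoms$chain == ch]
    steps <- diff(rn)
    if (any(steps < 0)) {
      stop("residue numbering must be non-decreasing within chain ", ch)
    }
    # per-residue plddt must be single-valued
    pl <- tapply(atoms$plddt[atoms$chain == ch], rn, function(v) diff(range(v)))
    if (any(pl > 1e-9)) {
      stop("pLDDT differs between atoms of one residue in chain ", ch)
    }
  }
  atoms$is_h <- toupper(atoms$element) == "H"

  structure(
    list(atoms = atoms, model_id = as.character(model_id),
         rank = as.integer(rank), subunits = subunits),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  rt <- residue_table(x)
  cat("structure_model ", x$model_id,
      if (!is.na(x$rank)) paste0(" (rank ", x$rank, ")"), "\n", sep = "")
  cat("  chains: ", paste(unique(x$atoms$chain), collapse = ", "),
      "; residues: ", nrow(rt), "; atoms: ", nrow(x$atoms), "\n", sep = "")
  cat("  mean pLDDT: ", sprintf("%.2f", mean_plddt(x)), "\n", sep = "")
  invisible(x)
}

#' Chain identifiers of a model
#' @param model a [structure_model()].
#' @return character vector of chain ids, in file order.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Per-residue table of a model
#'
#' One row per residue with its chain, author number, 3-letter code and
#' pLDDT confidence.
#'
#' @param model a [structure_model()].
#' @return data.frame with columns `chain`, `resno`, `resid`, `plddt`.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- !duplicated(paste(a$chain, a$resno))
  out <- a[key, c("chain", "resno", "resid", "plddt")]
  rownames(out) <- NULL
  out
}

#' Mean pLDDT of a model
#'
#' Mean of the per-residue confidence over all residues of all chains
#' (the key used to rank a set of predicted models).
#'
#' @param model a [structure_model()].
#' @return numeric scalar in [0, 100].
#' @export
mean_plddt <- function(model) mean(residue_table(model)$plddt)

# Internal: atoms of one chain, optionally heavy atoms only.
chain_atoms <- function(model, chain, heavy_only = TRUE) {
  a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("unknown chain id: ", chain)
  if (heavy_only) a <- a[!a$is_h, , drop = FALSE]
  a
}

# Internal: residue plddt lookup table keyed "chain|resno".
plddt_lookup <- function(model) {
  rt <- residue_table(model)
  stats::setNames(rt$plddt, paste(rt$chain, rt$resno, sep = "|"))
}
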