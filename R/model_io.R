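#' Read a predicted structure model
#'
#' Reads a PDB or mmCIF file into a [structure_model()]. Per-residue
#' confidence (pLDDT) is taken from the B-factor column, the convention
#' used by structure-prediction servers: the value on the CA atom if the
#' residue has one, otherwise the mean B-factor over the residue's atoms
#' (identical on real predicted models, which write one value per
#' residue). Author residue numbering is preserved verbatim.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension:
#'   `.cif`/`.mmcif` is mmCIF, anything else PDB).
#' @param model_id identifier for the returned model; defaults to the
#'   file name without extension.
#' @param subunits optional named character vector of chain -> subunit
#'   labels, attached as-is.
#'
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model_id = NULL, subunits = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, rm.alt = TRUE, verbose = FALSE))
    },
    error = function(e) stop("could not parse ", path, " as ", format, ": ",
                             conditionMessage(e))
  )
  a <- raw$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in ", path)
  if (any(!is.na(a$insert) & a$insert != "")) {
    stop("insertion codes are not supported (predicted models never carry them): ",
         path)
  }
  if (any(!is.finite(a$b))) {
    stop("no confidence data: blank B-factor column in ", path)
  }
  element <- a$elesy
  if (is.null(element) || all(is.na(element) | element == "")) {
    # fall back on the first letter of the atom name
    element <- sub("^[0-9]*", "", a$elety)
    element <- substr(element, 1L, 1L)
  }
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, resid = a$resid, eleno = a$eleno,
    elety = a$elety, element = element, x = a$x, y = a$y, z = a$z,
    plddt = NA_real_, stringsAsFactors = FALSE
  )
  # per-residue confidence: CA B-factor when present, else atom mean
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  for (k in unique(key)) {
    idx <- which(key == k)
    ca <- idx[atoms$elety[idx] == "CA"]
    atoms$plddt[idx] <- if (length(ca) >= 1L) a$b[ca[1L]] else mean(a$b[idx])
  }
  if (is.null(model_id)) model_id <- sub("\\.[^.]*$", "", basename(path))
  structure_model(atoms, model_id = model_id, subunits = subunits)
}

#' Write a structure model
#'
#' Writes PDB (fixed-width, via bio3d) or a minimal mmCIF `_atom_site`
#' loop. The per-residue pLDDT is written into the B-factor field with
#' two decimals; coordinates carry three decimals. `write_structure`
#' followed by [read_structure()] is an identity at that precision.
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  if (!inherits(model, "structure_model")) stop("model must be a structure_model")
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  a <- model$atoms
  if (format == "pdb") {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      resno = a$resno, chain = a$chain, resid = a$resid,
      eleno = a$eleno, elety = a$elety, elesy = a$element,
      o = rep(1, nrow(a)), b = a$plddt
    )
  } else {
    fields <- c("group_PDB", "id", "type_symbol", "label_atom_id",
                "label_alt_id", "label_comp_id", "label_asym_id",
                "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")
    rows <- sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f %d %s %s %s 1",
      a$eleno, a$element, a$elety, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, a$plddt, a$resno, a$resid, a$chain, a$elety
    )
    writeLines(c(
      paste0("data_", gsub("[^A-Za-z0-9_-]", "_", model$model_id)),
      "loop_", paste0("_atom_site.", fields), rows, "#"
    ), path)
  }
  invisible(path)
}

#' Read a predicted aligned error (PAE) matrix
#'
#' PAE is the square matrix of expected positional error (Angstrom)
#' between residue pairs of a predicted model; low off-diagonal blocks
#' indicate confident inter-chain placement. Two JSON dialects are
#' supported: the ColabFold convention (`predicted_aligned_error` or
#' `pae` as a list of lists, possibly wrapped in a one-element array)
#' and the AF3 server convention (`pae` plus `token_chain_ids`).
#'
#' @param path JSON file path.
#' @param dialect `"colabfold"`, `"af3"` or `"auto"`.
#' @param model optional [structure_model()] used to attach chain
#'   boundaries (residue index ranges per chain in concatenated order);
#'   for the AF3 dialect boundaries come from `token_chain_ids` when no
#'   model is given.
#' @return A `pae_matrix`: list with `values` (square numeric matrix)
#'   and `chain_boundaries` (named list of `c(first, last)` indices, or
#'   NULL).
#' @export
read_pae <- function(path, dialect = c("auto", "colabfold", "af3"),
                     model = NULL) {
  dialect <- match.arg(dialect)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  # ColabFold historically wraps the object in a length-1 array
  if (is.null(names(js)) && length(js) == 1L) js <- js[[1]]
  token_chains <- NULL
  if (dialect == "auto") {
    dialect <- if (!is.null(js$token_chain_ids)) "af3" else "colabfold"
  }
  if (dialect == "af3") {
    vals <- js$pae
    token_chains <- unlist(js$token_chain_ids)
  } else {
    vals <- if (!is.null(js$predicted_aligned_error)) js$predicted_aligned_error else js$pae
  }
  if (is.null(vals)) stop("no PAE matrix found in ", path)
  if (is.list(vals)) vals <- do.call(rbind, lapply(vals, as.numeric))
  vals <- as.matrix(vals)
  if (nrow(vals) != ncol(vals)) {
    stop("PAE matrix must be square; got ", nrow(vals), " x ", ncol(vals))
  }
  if (any(vals < 0)) stop("PAE entries must be >= 0")
  boundaries <- NULL
  if (!is.null(model)) {
    rt <- residue_table(model)
    if (nrow(rt) != nrow(vals)) {
      stop("PAE dimension (", nrow(vals), ") does not match model residue count (",
           nrow(rt), ")")
    }
    idx <- seq_len(nrow(rt))
    boundaries <- lapply(split(idx, rt$chain), range)
  } else if (!is.null(token_chains)) {
    idx <- seq_along(token_chains)
    boundaries <- lapply(split(idx, token_chains), range)
  }
  structure(list(values = unname(vals), chain_boundaries = boundaries),
            class = "pae_matrix")
}

#' Write a PAE matrix as JSON
#'
#' @param values square numeric matrix of expected position errors (A).
#' @param path output path.
#' @param dialect `"colabfold"` (list-of-lists under
#'   `predicted_aligned_error`) or `"af3"` (`pae` + `token_chain_ids`).
#' @param chain_ids for the AF3 dialect, a character vector of per-row
#'   chain ids (defaults to a single chain "A").
#' @return `path`, invisibly.
#' @export
write_pae <- function(values, path, dialect = c("colabfold", "af3"),
                      chain_ids = NULL) {
  dialect <- match.arg(dialect)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("PAE matrix must be square")
  if (any(values < 0)) stop("PAE entries must be >= 0")
  mat <- apply(values, 1L, as.numeric, simplify = FALSE)
  if (dialect == "colabfold") {
    obj <- list(predicted_aligned_error = mat,
                max_predicted_aligned_error = max(values))
  } else {
    if (is.null(chain_ids)) chain_ids <- rep("A", nrow(values))
    obj <- list(pae = mat, token_chain_ids = as.list(chain_ids),
                token_res_ids = as.list(seq_len(nrow(values))))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
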