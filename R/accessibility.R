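# van der Waals radii (A) for the elements found in predicted protein
# models; anything else falls back on the carbon radius with a warning.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.20, SE = 1.90)

# Theoretical maximum accessible surface areas per residue type (A^2),
# Tien et al. 2013 ("theoretical" column); used to normalize absolute
# SASA into relative SASA.
.max_asa_theoretical <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

# Deterministic quasi-uniform unit sphere points (golden-spiral /
# Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: each heavy atom's solvent-accessible sphere (radius =
#' van der Waals radius + probe radius) is sampled with a deterministic
#' golden-spiral lattice of `n_points` test points; a point is
#' accessible when it lies outside every neighbour's expanded sphere.
#' Atom areas are summed per residue; hydrogens are ignored.
#'
#' @param model a [structure_model()].
#' @param probe_radius solvent probe radius in Angstrom (default 1.4,
#'   water).
#' @param n_points test points per atom (default 960); results are
#'   deterministic for a fixed value.
#' @param max_asa named vector of per-residue-type maximum accessible
#'   areas used for the relative SASA column (default: theoretical
#'   maxima); residue types absent from the table get `NA` relative
#'   values.
#' @return A `sasa_result`: list with `residues` (data.frame `chain`,
#'   `resno`, `resid`, `sasa`, `rel_sasa`), `atom_sasa` (numeric per
#'   heavy atom), `probe_radius`, `n_points`, `max_asa_table`.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960L,
                         max_asa = .max_asa_theoretical) {
  a <- model$atoms[!model$atoms$is_h, , drop = FALSE]
  if (nrow(a) == 0L) stop("model has no heavy atoms")
  el <- toupper(a$element)
  unknown <- setdiff(unique(el), names(.vdw_radii))
  if (length(unknown) > 0L) {
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using carbon radius 1.7 A")
  }
  radii <- unname(.vdw_radii[el])
  radii[is.na(radii)] <- .vdw_radii[["C"]]
  ext <- radii + probe_radius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  # neighbour lists from the squared distance matrix
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    cut <- (ext[i] + ext)^2
    nb <- which(d2[i, ] < cut)
    nb <- nb[nb != i]
    test <- sweep(pts * ext[i], 2L, xyz[i, ], "+")
    if (length(nb) > 0L) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dx <- test[free, 1] - xyz[j, 1]
        dy <- test[free, 2] - xyz[j, 2]
        dz <- test[free, 3] - xyz[j, 3]
        dd <- dx * dx + dy * dy + dz * dz
        # ties (a point exactly on a neighbour's sphere, e.g. coincident
        # atoms) go to the lower-numbered atom, so an overlapping pair
        # still contributes one sphere's worth of surface
        blocked <- dd < ext[j]^2 - 1e-9 | (abs(dd - ext[j]^2) <= 1e-9 & j < i)
        free[free] <- !blocked
      }
      n_free <- sum(free)
    } else {
      n_free <- n_points
    }
    atom_sasa[i] <- 4 * pi * ext[i]^2 * n_free / n_points
  }
  key <- paste(a$chain, a$resno, sep = "|")
  first <- !duplicated(key)
  res <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    resid = a$resid[first], stringsAsFactors = FALSE)
  res$sasa <- as.numeric(tapply(atom_sasa, key, sum)[key[first]])
  res$rel_sasa <- res$sasa / unname(max_asa[res$resid])
  rownames(res) <- NULL
  structure(
    list(residues = res, atom_sasa = atom_sasa, probe_radius = probe_radius,
         n_points = as.integer(n_points),
         max_asa_table = deparse(substitute(max_asa))),
    class = "sasa_result"
  )
}

#' Relative solvent accessibility
#'
#' Absolute SASA divided by the residue-type maximum accessible area.
#'
#' @param sasa absolute SASA values (A^2).
#' @param resid 3-letter residue codes, recycled against `sasa`.
#' @param max_asa named maximum-ASA table (default theoretical maxima).
#' @return numeric vector of fractions (can exceed 1 for extended
#'   conformations).
#' @export
relative_sasa <- function(sasa, resid, max_asa = .max_asa_theoretical) {
  m <- max_asa[resid]
  if (any(is.na(m))) {
    stop("residue type(s) not in the max-ASA table: ",
         paste(unique(resid[is.na(m)]), collapse = ", "),
         "; table covers: ", paste(names(max_asa), collapse = ", "))
  }
  unname(sasa / m)
}

#' Map pairwise-interface residues onto an assembled complex
#'
#' Applies explicit per-subunit numbering offsets and kept ranges
#' (mirroring deliberate truncations made to fit complex-prediction
#' size limits) to translate interface residues from the pairwise
#' models into the assembled complex model. Mapping is never inferred
#' by alignment; residue-name mismatches are a hard error (off-by-one
#' guard), residues falling in trimmed ranges are reported unmappable.
#'
#' @param interface_residues data.frame with columns `subunit`,
#'   `seq_index`, `resid` (name in the pairwise model).
#' @param complex the assembled [structure_model()].
#' @param offsets named list (by subunit) of lists with `chain` (chain
#'   id in the complex), `offset` (integer added to the pairwise
#'   numbering; default 0) and optional `keep` (list of `c(first,
#'   last)` source ranges retained in the complex; default: everything).
#' @return list with `mapping` (data.frame `subunit`, `seq_index`,
#'   `resid`, `chain`, `target_index`) and `unmappable` (data.frame
#'   `subunit`, `seq_index`, `reason`).
#' @export
map_interface_residues <- function(interface_residues, complex, offsets) {
  rt <- residue_table(complex)
  rt_key <- paste(rt$chain, rt$resno, sep = "|")
  map_rows <- list(); un_rows <- list()
  for (i in seq_len(nrow(interface_residues))) {
    su <- interface_residues$subunit[i]
    si <- interface_residues$seq_index[i]
    nm <- interface_residues$resid[i]
    cfg <- offsets[[su]]
    if (is.null(cfg)) {
      un_rows[[length(un_rows) + 1L]] <-
        data.frame(subunit = su, seq_index = si,
                   reason = "no offset config for subunit")
      next
    }
    off <- if (is.null(cfg$offset)) 0L else as.integer(cfg$offset)
    kept <- TRUE
    if (!is.null(cfg$keep)) {
      kept <- any(vapply(cfg$keep, function(r) si >= r[1] && si <= r[2],
                         logical(1)))
    }
    if (!kept) {
      un_rows[[length(un_rows) + 1L]] <-
        data.frame(subunit = su, seq_index = si, reason = "inside trimmed range")
      next
    }
    ti <- si + off
    hit <- match(paste(cfg$chain, ti, sep = "|"), rt_key)
    if (is.na(hit)) {
      un_rows[[length(un_rows) + 1L]] <-
        data.frame(subunit = su, seq_index = si,
                   reason = paste0("no residue ", ti, " in complex chain ",
                                   cfg$chain))
      next
    }
    if (!identical(rt$resid[hit], nm)) {
      stop("residue-name mismatch mapping ", su, " ", si, " (", nm,
           ") onto complex ", cfg$chain, " ", ti, " (", rt$resid[hit],
           "): check the offsets")
    }
    map_rows[[length(map_rows) + 1L]] <-
      data.frame(subunit = su, seq_index = si, resid = nm,
                 chain = cfg$chain, target_index = ti,
                 stringsAsFactors = FALSE)
  }
  mapping <- if (length(map_rows) > 0L) do.call(rbind, map_rows) else
    data.frame(subunit = character(), seq_index = integer(),
               resid = character(), chain = character(),
               target_index = integer())
  if (anyDuplicated(paste(mapping$chain, mapping$target_index))) {
    stop("mapping collision: two interface residues map onto the same ",
         "complex residue")
  }
  unmappable <- if (length(un_rows) > 0L) do.call(rbind, un_rows) else
    data.frame(subunit = character(), seq_index = integer(),
               reason = character())
  rownames(mapping) <- rownames(unmappable) <- NULL
  list(mapping = mapping, unmappable = unmappable)
}

#' Steric feasibility of mapped interface residues
#'
#' Classifies each mapped interface residue as accessible on the
#' assembled complex surface (relative SASA in complex context at or
#' above `rsa_threshold`) and summarizes the percentage accessible.
#' This is the quantitative surrogate for judging whether predicted
#' binding sites remain available on the assembled complex.
#'
#' @param mapped result of [map_interface_residues()], or its `mapping`
#'   data.frame.
#' @param sasa a `sasa_result` computed on the same complex model.
#' @param rsa_threshold relative-SASA threshold (default 0.25).
#' @param complex_id label for the report.
#' @return A `feasibility_report`: list with `complex_id`, `residues`
#'   (data.frame with `rel_sasa` and `accessible`),
#'   `percent_accessible` (0-100, over mapped residues only),
#'   `n_unmappable`, `rsa_threshold`, `max_asa_table`.
#' @export
feasibility_percent <- function(mapped, sasa, rsa_threshold = 0.25,
                                complex_id = "complex") {
  mapping <- if (is.data.frame(mapped)) mapped else mapped$mapping
  n_unmap <- if (is.data.frame(mapped)) 0L else nrow(mapped$unmappable)
  if (nrow(mapping) == 0L) {
    stop("no mapped residues: percent accessible is undefined")
  }
  res <- sasa$residues
  idx <- match(paste(mapping$chain, mapping$target_index),
               paste(res$chain, res$resno))
  if (any(is.na(idx))) stop("mapped residue missing from the SASA result")
  out <- cbind(mapping,
               rel_sasa = res$rel_sasa[idx],
               accessible = res$rel_sasa[idx] >= rsa_threshold)
  structure(
    list(complex_id = complex_id, residues = out,
         percent_accessible = 100 * mean(out$accessible),
         n_unmappable = n_unmap, rsa_threshold = rsa_threshold,
         max_asa_table = sasa$max_asa_table),
    class = "feasibility_report"
  )
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat("feasibility_report ", x$complex_id, ": ",
      sprintf("%.1f", x$percent_accessible), "% of ", nrow(x$residues),
      " mapped interface residues accessible (rel. SASA >= ",
      x$rsa_threshold, "); ", x$n_unmappable, " unmappable\n", sep = "")
  invisible(x)
}
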