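#' Structure model
#'
#' A light container for one structural model: an atom table plus chain-role
#' annotations. Per-atom confidence (e.g. pLDDT) is carried in the `conf`
#' column; per-residue confidence is its mean over the residue's atoms.
#'
#' @param model_id model identifier.
#' @param atoms data.frame with columns `chain`, `resno` (mature numbering),
#'   `resid` (3-letter residue name), `atom` (atom name), `element`, `x`,
#'   `y`, `z` (Angstrom), `conf` (per-atom confidence; may be `NA`).
#' @param chain_roles named character vector mapping roles to chain ids,
#'   e.g. `c(receptor = "R", chemokine = "C")`.
#' @param rank_score optional prediction-confidence score for ranking.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(model_id, atoms, chain_roles, rank_score = NA_real_) {
  req <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z", "conf")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in model ", model_id)
  if (is.null(names(chain_roles)) || !"receptor" %in% names(chain_roles))
    stop("chain_roles must name at least a 'receptor' chain")
  absent <- setdiff(unname(chain_roles), unique(atoms$chain))
  if (length(absent))
    stop("declared chain(s) not present in model ", model_id, ": ",
         paste(absent, collapse = ", "))
  atoms$resno <- as.integer(atoms$resno)
  structure(list(model_id = model_id, atoms = atoms,
                 chain_roles = chain_roles, rank_score = rank_score),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, chains [%s]\n", x$model_id,
              nrow(x$atoms),
              paste(sprintf("%s=%s", names(x$chain_roles), x$chain_roles),
                    collapse = ", ")))
  invisible(x)
}

#' Per-residue mean confidence of a model
#'
#' @param model a [structure_model].
#' @param chain optional chain restriction.
#' @return data.frame with `chain`, `resno`, `confidence`.
#' @export
residue_confidence <- function(model, chain = NULL) {
  at <- model$atoms
  if (!is.null(chain)) at <- at[at$chain == chain, ]
  agg <- stats::aggregate(conf ~ chain + resno, data = at, FUN = mean)
  names(agg)[3] <- "confidence"
  agg[order(agg$chain, agg$resno), ]
}

#' Model ensemble
#'
#' An ordered list of models sharing identical receptor-chain topology,
#' optionally with an inactive-state reference structure.
#'
#' @param models list of [structure_model]s (non-empty).
#' @param receptor_chain,chemokine_chain chain ids.
#' @param reference_inactive optional [structure_model] of the inactive state.
#' @return Object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(models, receptor_chain, chemokine_chain = NULL,
                               reference_inactive = NULL) {
  if (!length(models)) stop("ensemble must contain at least one model")
  key <- function(m) {
    at <- m$atoms[m$atoms$chain == receptor_chain, ]
    paste(at$chain, at$resno, at$atom, sep = "|")
  }
  k0 <- key(models[[1]])
  for (m in models[-1])
    if (!identical(key(m), k0))
      stop("model ", m$model_id,
           ": receptor-chain topology differs from first model")
  structure(list(models = models, receptor_chain = receptor_chain,
                 chemokine_chain = chemokine_chain,
                 reference_inactive = reference_inactive),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d models (receptor chain %s%s)\n",
              length(x$models), x$receptor_chain,
              if (!is.null(x$reference_inactive)) ", inactive reference" else ""))
  invisible(x)
}

# element from an atom name when the file does not state it
.element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("FE", "ZN", "MG", "SE"), two, substr(nm, 1, 1))
}

#' Read a structure file (PDB or mmCIF)
#'
#' Fixed-column PDB files are parsed with \pkg{bio3d}; mmCIF files with a
#' minimal `atom_site` reader sufficient for model coordinates. The B-factor
#' column is mapped to per-atom confidence when `confidence_from_b` is set
#' (the convention used by predicted-model files, where B carries pLDDT).
#'
#' @param path structure file (`.pdb`, `.ent`, `.cif`, `.mmcif`).
#' @param chain_roles named character vector, e.g.
#'   `c(receptor = "A", chemokine = "B")`; all named chains must exist.
#' @param confidence_from_b logical; read per-atom confidence from B.
#' @param model_id defaults to the file name without extension.
#' @return A [structure_model].
#' @export
read_structure <- function(path, chain_roles, confidence_from_b = TRUE,
                           model_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(model_id))
    model_id <- sub("\\.[^.]*$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  atoms <- if (ext %in% c("cif", "mmcif")) .read_mmcif_atoms(path)
           else .read_pdb_atoms(path)
  atoms$conf <- if (confidence_from_b) atoms$b else NA_real_
  atoms$b <- NULL
  structure_model(model_id, atoms, chain_roles)
}

.read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), ]
  el <- trimws(at$elesy)
  el[is.na(el) | el == ""] <- .element_from_name(at$elety[is.na(el) | el == ""])
  data.frame(chain = at$chain, resno = as.integer(at$resno), resid = at$resid,
             atom = trimws(at$elety), element = el,
             x = at$x, y = at$y, z = at$z, b = at$b,
             stringsAsFactors = FALSE)
}

.read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fld_idx <- grep("^_atom_site\\.", lines)
  if (!length(fld_idx)) stop("no _atom_site loop in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[fld_idx]))
  body <- lines[seq(max(fld_idx) + 1L, length(lines))]
  stopline <- grep("^(loop_|#|_)", body)
  if (length(stopline)) body <- body[seq_len(min(stopline) - 1L)]
  body <- body[nzchar(trimws(body))]
  toks <- strsplit(trimws(body), "[[:space:]]+")
  bad <- which(vapply(toks, length, 1L) != length(fields))
  if (length(bad))
    stop("mmCIF parse error in ", path, ": atom_site row ", bad[1],
         " (file line ", max(fld_idx) + bad[1], ") has ",
         length(toks[[bad[1]]]), " tokens, expected ", length(fields))
  tab <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
  names(tab) <- fields
  pick <- function(...) {
    for (f in c(...)) if (f %in% fields) return(tab[[f]])
    stop("mmCIF ", path, " lacks atom_site field(s): ",
         paste(c(...), collapse = "/"))
  }
  unquote <- function(x) gsub('^"|"$', "", x)
  data.frame(chain = pick("auth_asym_id", "label_asym_id"),
             resno = as.integer(pick("auth_seq_id", "label_seq_id")),
             resid = pick("label_comp_id"),
             atom = unquote(pick("auth_atom_id", "label_atom_id")),
             element = pick("type_symbol"),
             x = as.numeric(pick("Cartn_x")),
             y = as.numeric(pick("Cartn_y")),
             z = as.numeric(pick("Cartn_z")),
             b = suppressWarnings(as.numeric(pick("B_iso_or_equiv"))),
             stringsAsFactors = FALSE)
}

#' Write a structure model to PDB or mmCIF
#'
#' Fixture-grade writer: fixed-column PDB `ATOM` records, or a minimal mmCIF
#' `atom_site` loop. Per-atom confidence is written into the B column.
#'
#' @param model a [structure_model].
#' @param path output file.
#' @param format `"pdb"` or `"cif"`; default from the file extension.
#' @export
write_structure <- function(model, path, format = NULL) {
  at <- model$atoms
  if (is.null(format)) {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  conf <- ifelse(is.na(at$conf), 0, at$conf)
  if (format == "pdb") {
    # atom-name column convention: 1/2-letter elements start in col 14
    nm <- ifelse(nchar(at$atom) >= 4, at$atom, sprintf(" %-3s", at$atom))
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), nm, at$resid, at$chain, at$resno,
      at$x, at$y, at$z, 1.00, conf, at$element)
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c("data_model", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_comp_id", "auth_asym_id", "auth_seq_id",
                      "Cartn_x", "Cartn_y", "Cartn_z", "B_iso_or_equiv")))
    rows <- sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f %.2f",
                    seq_len(nrow(at)), at$element, at$atom, at$resid,
                    at$chain, at$resno, at$x, at$y, at$z, conf)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}
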