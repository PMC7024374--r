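# Readers and writers: FASTA sequences and multi-model coarse PDB ensembles.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of one-letter sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

.pdb_atom_name <- function(lay_row) {
  if (lay_row$type == "CA") "CA" else if (lay_row$is_sg) "SG" else "SC"
}

#' Write an ensemble as a multi-model PDB file
#'
#' MODEL/ENDMDL blocks with one ATOM record per particle: \code{CA} for the
#' backbone, \code{SG} for cysteine side chains, \code{SC} otherwise;
#' residues numbered from 1. Each model carries its energy in a REMARK line.
#' Coordinates are written at the format's 3-decimal precision.
#'
#' @param e a [generate_ensemble()] result (or a \code{coarse_model}).
#' @param path output path.
#' @return invisibly \code{path}.
#' @export
write_pdb <- function(e, path) {
  if (inherits(e, "coarse_model")) {
    e <- structure(list(models = list(e$coords), energies = NA_real_,
                        layout = e$layout, sequence = e$sequence),
                   class = "cg_ensemble")
  }
  stopifnot(inherits(e, "cg_ensemble"))
  lay <- e$layout
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(e$models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    if (!is.na(e$energies[m])) {
      writeLines(sprintf("REMARK 250 ENERGY %.6f", e$energies[m]), con)
    }
    xyz <- e$models[[m]]
    for (k in seq_len(nrow(lay))) {
      nm <- .pdb_atom_name(lay[k, ])
      el <- if (nm == "SG") "S" else "C"
      writeLines(sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                         k, nm, .AA_THREE[lay$code[k]], lay$res[k],
                         xyz[k, 1], xyz[k, 2], xyz[k, 3], 1.0, 0.0, el), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model coarse PDB ensemble
#'
#' Inverse of [write_pdb()]: parses MODEL/ENDMDL blocks of ATOM records with
#' CA and SC/SG particles into an ensemble. Coordinates round-trip within the
#' format's 1e-3 A precision.
#'
#' @param path PDB file path.
#' @return a \code{cg_ensemble}.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  three_to_one <- stats::setNames(names(.AA_THREE), .AA_THREE)
  models <- list()
  energies <- numeric()
  cur <- NULL
  cur_energy <- NA_real_
  seq_codes <- NULL
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    if (startsWith(l, "MODEL")) {
      cur <- list(); cur_energy <- NA_real_
    } else if (startsWith(l, "REMARK 250 ENERGY")) {
      cur_energy <- as.numeric(sub("REMARK 250 ENERGY", "", l))
    } else if (startsWith(l, "ATOM")) {
      if (is.null(cur)) stop("ATOM record outside MODEL block at line ", ln)
      nm <- trimws(substr(l, 13, 16))
      res3 <- trimws(substr(l, 18, 20))
      resno <- suppressWarnings(as.integer(substr(l, 23, 26)))
      xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))))
      if (is.na(resno) || anyNA(xyz) || !res3 %in% names(three_to_one) ||
          !nm %in% c("CA", "SC", "SG")) {
        stop("malformed ATOM record at line ", ln, ": '", l, "'")
      }
      cur[[length(cur) + 1L]] <- list(nm = nm, code = three_to_one[[res3]],
                                      res = resno, xyz = xyz)
    } else if (startsWith(l, "ENDMDL")) {
      if (is.null(cur)) stop("ENDMDL without MODEL at line ", ln)
      cas <- Filter(function(a) a$nm == "CA", cur)
      codes <- vapply(cas[order(vapply(cas, `[[`, integer(1), "res"))], `[[`, character(1), "code")
      if (is.null(seq_codes)) seq_codes <- codes
      else if (!identical(codes, seq_codes)) stop("models carry different sequences")
      models[[length(models) + 1L]] <- cur
      energies <- c(energies, cur_energy)
      cur <- NULL
    }
  }
  if (!length(models)) stop("no MODEL blocks found in ", path)
  sequence <- paste(seq_codes, collapse = "")
  lay <- coarse_layout(sequence)
  coord_list <- lapply(models, function(atoms) {
    xyz <- matrix(NA_real_, nrow(lay), 3)
    for (a in atoms) {
      type <- if (a$nm == "CA") "CA" else "SC"
      k <- lay$particle[lay$res == a$res & lay$type == type]
      if (!length(k)) stop("unexpected atom ", a$nm, " at residue ", a$res)
      xyz[k, ] <- a$xyz
    }
    if (anyNA(xyz)) {
      miss <- lay[is.na(xyz[, 1]), ]
      stop("missing particle(s) in model, e.g. ", miss$type[1],
           " (", if (miss$is_sg[1]) "SG" else miss$type[1], ") of residue ", miss$res[1],
           "; the disulfide caller needs SG side-chain atoms for every cysteine")
    }
    xyz
  })
  structure(list(models = coord_list, energies = energies, layout = lay,
                 sequence = sequence, seeds = NA_integer_, config = NULL, ss = NULL),
            class = "cg_ensemble")
}
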