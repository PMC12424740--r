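#' Read a PDB file
#'
#' Parses ATOM/HETATM records through bio3d, returning the C-alpha trace
#' per model with residue identities as tokens. Residue numbering is
#' preserved as 1-based author numbering; chain identifiers are kept.
#'
#' @param path path to a PDB file.
#' @return an object of class `pdb_record`: list with `models` (list of
#'   L x 3 C-alpha coordinate matrices), `tokens`, `resno`, `chain`,
#'   `n_models`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("malformed PDB file '", path,
                                           "': ", conditionMessage(e)))
  ca <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  at <- pdb$atom[ca$atom, , drop = FALSE]
  tokens <- match(bio3d::aa321(at$resid), aa_alphabet())
  tokens[is.na(tokens)] <- mask_token()
  n_models <- nrow(pdb$xyz)
  models <- lapply(seq_len(n_models), function(m) {
    matrix(pdb$xyz[m, ca$xyz], ncol = 3L, byrow = TRUE)
  })
  structure(list(models = models, tokens = as.integer(tokens),
                 resno = at$resno, chain = at$chain,
                 n_models = n_models),
            class = "pdb_record")
}

#' @export
print.pdb_record <- function(x, ...) {
  cat(sprintf("pdb_record: %d residues, %d model(s), chain(s) %s\n",
              length(x$tokens), x$n_models,
              paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' Write a C-alpha trace as PDB
#'
#' One structure writes a single model; a list of structures (e.g. the
#' two conformers of a coupled design) writes consecutive MODEL blocks
#' sharing residue numbering. Coordinates are written at the format's
#' 1e-3 Angstrom precision.
#'
#' @param path output path.
#' @param structures L x 3 matrix, `structure_state`, or list of these.
#' @param tokens length-L amino-acid tokens.
#' @param chain chain identifier (single chain).
#' @return the path, invisibly.
#' @export
write_pdb <- function(path, structures, tokens, chain = "A") {
  if (!is.list(structures) || inherits(structures, "structure_state")) {
    structures <- list(structures)
  }
  coords <- lapply(structures, .coords_of)
  L <- nrow(coords[[1L]])
  stopifnot(all(vapply(coords, nrow, integer(1)) == L),
            length(tokens) == L)
  tokens <- .tokens_of(tokens)
  resid3 <- bio3d::aa123(c(aa_alphabet(), "X")[pmin(tokens, 21L)])
  resid3[tokens == mask_token()] <- "UNK"
  xyz <- do.call(rbind, lapply(coords, function(m) as.vector(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = seq_len(L),
                   resid = resid3, chain = rep(chain, L),
                   elety = rep("CA", L))
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings keeping the package's integer token
#' representation at the boundary.
#'
#' @param path file path.
#' @param sequences named list (or single vector) of token vectors.
#' @return `read_fasta()` returns a named list of token vectors.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- lapply(as.character(ss), string_to_tokens)
  names(out) <- names(ss)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(path, sequences) {
  if (!is.list(sequences)) sequences <- list(seq1 = sequences)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  ss <- Biostrings::AAStringSet(vapply(sequences, function(s) {
    tokens_to_string(.tokens_of(s))
  }, character(1)))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an OBO-dialect ontology (is_a edges only)
#'
#' Minimal parser for the `[Term]` stanzas of an OBO file: extracts term
#' ids, names, and `is_a` parent relationships; obsolete terms are
#' skipped. Only the edge types needed for annotation propagation are
#' read.
#'
#' @param path path to an OBO file.
#' @return list with `parents` (named list term -> parent ids) and
#'   `names` (named character vector).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parents <- list(); nm <- character(0)
  cur <- NULL; cur_parents <- character(0); cur_name <- NA_character_
  obsolete <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      parents[[cur]] <<- cur_parents
      nm[cur] <<- cur_name
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- NULL; cur_parents <- character(0); cur_name <- NA_character_
      obsolete <- FALSE; in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(); cur <- NULL; in_term <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id:")) {
        cur <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "name:")) {
        cur_name <- trimws(sub("^name:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        cur_parents <- c(cur_parents, tgt)
      } else if (grepl("^is_obsolete:\\s*true", ln)) {
        obsolete <- TRUE
      }
    }
  }
  flush()
  list(parents = parents, names = nm)
}

#' Run configuration
#'
#' A serializable record of everything needed to reproduce a run: task,
#' model/schedule settings, seed, and output directory. Saved as JSON
#' next to every set of outputs.
#'
#' @param task one of the supported workflows.
#' @param seed integer seed.
#' @param out output directory.
#' @param ... further named settings (lengths, steps, guidance strength,
#'   annealing, file paths).
#' @return an object of class `run_config`.
#' @export
run_config <- function(task = c("train", "sample-seq", "sample-struct",
                                "cogenerate", "inverse-fold", "couple",
                                "eval-site", "make-fixtures"),
                       seed = 1L, out = ".", ...) {
  task <- match.arg(task)
  structure(c(list(task = task, seed = as.integer(seed), out = out),
              list(...)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj)
}

#' Write design outputs
#'
#' Writes each design's structure(s) as PDB (coupled designs: two MODEL
#' blocks sharing residue numbering), its sequence as FASTA, metrics as
#' tab-delimited text, and the archived configuration (with seed) as
#' JSON, so a run is reproducible from its output directory.
#'
#' @param designs list of designs, each with `sequence` (tokens or
#'   `sequence_state`) and `structures` (list of coordinate matrices or
#'   `structure_state`s); optional `name`.
#' @param dir output directory (created if needed).
#' @param metrics optional data frame of per-design metrics.
#' @param config optional [run_config()] to archive.
#' @return character vector of written paths, invisibly.
#' @export
write_outputs <- function(designs, dir, metrics = NULL, config = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  paths <- character(0)
  seqs <- list()
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    nm <- if (!is.null(d$name)) d$name else sprintf("design_%03d", i)
    pp <- file.path(dir, paste0(nm, ".pdb"))
    write_pdb(pp, d$structures, .tokens_of(d$sequence))
    paths <- c(paths, pp)
    seqs[[nm]] <- .tokens_of(d$sequence)
  }
  fp <- file.path(dir, "designs.fasta")
  write_fasta(fp, seqs)
  paths <- c(paths, fp)
  if (!is.null(metrics)) {
    mp <- file.path(dir, "metrics.tsv")
    utils::write.table(metrics, mp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, mp)
  }
  if (!is.null(config)) {
    cp <- file.path(dir, "run_config.json")
    save_run_config(config, cp)
    paths <- c(paths, cp)
  }
  invisible(paths)
}
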