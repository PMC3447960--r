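#' Read a particle structure from PDB or GRO
#'
#' All internal lengths are nm: PDB coordinates (Angstrom) are multiplied
#' by 0.1 on reading, GRO coordinates are native nm. Residue indices are
#' 1-based as stored in the file. PDB parsing is backed by
#' \pkg{bio3d}; GRO files (which have no chain field) infer chains from
#' residue-number resets. Duplicate residue indices within a chain are an
#' error.
#'
#' @param path file path.
#' @param format `"pdb"` or `"gro"`; guessed from the extension by default.
#' @param domain_map optional named residue-range list used to annotate
#'   the `domain` column (files do not carry domain labels).
#' @return A `particle_model` tibble.
#' @export
read_structure <- function(path, format = NULL, domain_map = NULL) {
  format <- format %||% guess_format(path)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- switch(format,
    pdb = read_pdb_particles(path),
    gro = read_gro_particles(path),
    abort(sprintf("unsupported format '%s'", format))
  )
  df$domain <- if (is.null(domain_map)) {
    df$domain %||% "unassigned"
  } else {
    domain_labels(domain_map, df$resid)
  }
  as_particle_model(df[, c("chain", "resid", "domain", "species",
                           "x", "y", "z")])
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "gro") return("gro")
  abort(sprintf("cannot guess format from extension '.%s'", ext))
}

read_pdb_particles <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  tibble::tibble(
    chain = chain, resid = as.integer(a$resno),
    domain = NA_character_, species = a$resid,
    x = a$x * 0.1, y = a$y * 0.1, z = a$z * 0.1
  )
}

read_gro_particles <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) abort("malformed GRO file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) abort("malformed GRO file: line 2 is not an atom count")
  if (length(lines) < 2 + n + 1) {
    abort(sprintf("malformed GRO file: %d atom lines promised, %d present (line 2)",
                  n, length(lines) - 3))
  }
  body <- lines[3:(2 + n)]
  resno <- suppressWarnings(as.integer(substr(body, 1, 5)))
  resnm <- trimws(substr(body, 6, 10))
  x <- suppressWarnings(as.numeric(substr(body, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(body, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(body, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    abort(sprintf("malformed GRO record at line %d", bad[1] + 2))
  }
  # GRO has no chain field: residue-number resets start a new chain
  chain_idx <- cumsum(c(TRUE, diff(resno) < 0))
  tibble::tibble(
    chain = chain_letters(chain_idx), resid = resno,
    domain = NA_character_, species = resnm, x = x, y = y, z = z
  )
}

chain_letters <- function(i) {
  if (max(i) <= 26) LETTERS[i] else paste0("C", i)
}

#' Write a particle structure to PDB or GRO
#'
#' Writes one record per particle. PDB output is in Angstrom (nm x 10)
#' with atom name `CA` for receptor models; vesicle configurations use the
#' lipid species as the residue name and atom name `P` (one record per
#' headgroup). GRO output is native nm with a bounding-cube box line.
#'
#' @param x a `particle_model` or `vesicle`.
#' @param path output path.
#' @param format `"pdb"` or `"gro"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = NULL) {
  format <- format %||% guess_format(path)
  df <- io_records(x)
  lines <- switch(format,
    pdb = pdb_lines(df),
    gro = gro_lines(df),
    abort(sprintf("unsupported format '%s'", format))
  )
  writeLines(lines, path)
  invisible(path)
}

io_records <- function(obj) {
  if (inherits(obj, "vesicle")) {
    tibble::tibble(
      chain = "L", resid = seq_len(nrow(obj$lipids)),
      resname = substr(sub("^CL$", "CDL", obj$lipids$species), 1, 4),
      name = "P", x = obj$lipids$x, y = obj$lipids$y, z = obj$lipids$z
    )
  } else {
    stopifnot(inherits(obj, "particle_model") || is.data.frame(obj))
    tibble::tibble(
      chain = substr(obj$chain, 1, 1), resid = obj$resid,
      resname = "GLY", name = "CA", x = obj$x, y = obj$y, z = obj$z
    )
  }
}

pdb_lines <- function(df) {
  serial <- ((seq_len(nrow(df)) - 1) %% 99999) + 1
  resid <- ((df$resid - 1) %% 9999) + 1
  c(sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, substr(df$name, 1, 4), substr(df$resname, 1, 4),
            df$chain, resid, df$x * 10, df$y * 10, df$z * 10, 1, 0),
    "END")
}

gro_lines <- function(df) {
  # GRO residue/atom ids wrap at 5 digits
  resid <- ((df$resid - 1) %% 99999) + 1
  serial <- ((seq_len(nrow(df)) - 1) %% 99999) + 1
  box <- max(abs(c(df$x, df$y, df$z, 1))) * 2 + 2
  c("generated by rodbend",
    sprintf("%5d", nrow(df)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            resid, substr(df$resname, 1, 5), substr(df$name, 1, 5),
            serial, df$x, df$y, df$z),
    sprintf("%10.5f%10.5f%10.5f", box, box, box))
}

#' Write an ensemble as a multi-model PDB
#'
#' Multi-model PDB is the canonical trajectory interchange format here:
#' each frame becomes one `MODEL`/`ENDMDL` block.
#'
#' @param ensemble an `ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ensemble"))
  blocks <- purrr::map(seq_along(ensemble$coords), function(i) {
    df <- io_records(ensemble_frame(ensemble, i))
    body <- pdb_lines(df)
    c(sprintf("MODEL     %4d", i), body[-length(body)], "ENDMDL")
  })
  writeLines(c(unlist(blocks), "END"), path)
  invisible(path)
}

#' Read a trajectory into an ensemble
#'
#' Accepts a single multi-model PDB (each `MODEL` block becomes a frame)
#' or a character vector of single-frame PDB/GRO paths. All frames must
#' share the topology (same chains and residue indices in the same order);
#' the first offending frame is named otherwise.
#'
#' @param path one multi-model PDB path, or a vector of frame paths.
#' @param times optional frame times in ns (defaults to 0, 1, 2, ...).
#' @param domain_map optional domain annotation (see [read_structure()]).
#' @return An `ensemble`.
#' @export
read_ensemble <- function(path, times = NULL, domain_map = NULL) {
  if (length(path) == 1) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    first <- read_structure(path, domain_map = domain_map)
    nf <- nrow(pdb$xyz)
    coords <- lapply(seq_len(nf), function(i) {
      matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) * 0.1
    })
    topo <- first[, c("chain", "resid", "domain")]
  } else {
    models <- lapply(path, read_structure, domain_map = domain_map)
    topo <- models[[1]][, c("chain", "resid", "domain")]
    for (i in seq_along(models)[-1]) {
      ti <- models[[i]][, c("chain", "resid")]
      if (!identical(as.data.frame(ti), as.data.frame(topo[, c("chain", "resid")]))) {
        abort(sprintf("frame %d (%s) does not share the topology of frame 1",
                      i, path[i]))
      }
    }
    coords <- lapply(models, model_coords)
  }
  new_ensemble(topo, coords, times %||% (seq_along(coords) - 1))
}
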