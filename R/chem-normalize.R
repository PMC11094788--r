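# Molecular normalization: SMILES canonicalization through OpenBabel
# (ChemmineOB), atom-map / stereo stripping, name resolution and catalyst
# unification. Canonical SMILES here always means the OpenBabel canonical
# form of the map-stripped structure.

# per-session canonicalization cache: raw string -> canonical string (NA = invalid)
.canon_cache <- new.env(parent = emptyenv())

# One batched OpenBabel conversion. Each input line carries a synthetic title
# so that outputs can be realigned after invalid lines are skipped (`e`
# keeps OpenBabel going past parse failures).
ob_canonicalize_batch <- function(smiles) {
  ids <- paste0("m", seq_along(smiles))
  src <- paste0(paste(smiles, ids), "\n", collapse = "")
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "CAN", src,
      options = data.frame(names = "e", args = "", stringsAsFactors = FALSE)
    )),
    error = function(e) ""
  )
  res <- rep(NA_character_, length(smiles))
  lines <- strsplit(out %||% "", "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got_id <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "", character(1))
    got_smi <- vapply(parts, function(p) p[[1L]], character(1))
    m <- match(ids, got_id)
    ok <- !is.na(m)
    res[ok] <- got_smi[m[ok]]
  }
  res
}

#' Canonicalize SMILES strings
#'
#' Sanitizes and canonicalizes SMILES via OpenBabel. The result is a fixed
#' point: `canonicalize_smiles(canonicalize_smiles(s))` equals
#' `canonicalize_smiles(s)`, and all equivalent atom-order rewritings of a
#' molecule map to the same string. Atom-map indices (e.g. `[CH3:1]`) are
#' dropped by canonicalization; use [strip_atom_maps()] first if you need the
#' intermediate form. Chemically unparsable strings yield `NA`, never a
#' silent passthrough.
#'
#' Unique inputs are canonicalized once per session and cached, so repeated
#' calls over large record sets are cheap.
#'
#' @param smiles Character vector of SMILES strings (multi-fragment strings
#'   with `.` are allowed). `NA` and empty strings yield `NA`.
#' @return Character vector of canonical SMILES, `NA` where invalid.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("C(C)O", "CCO", "C1CC"))  # "CCO" "CCO" NA
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  x <- trimws(as.character(smiles))
  out <- rep(NA_character_, length(x))
  todo <- !is.na(x) & nzchar(x)
  if (!any(todo)) return(out)
  keys <- unique(x[todo])
  hit <- vapply(keys, exists, logical(1), envir = .canon_cache, inherits = FALSE)
  if (any(!hit)) {
    miss <- keys[!hit]
    vals <- ob_canonicalize_batch(miss)
    for (i in seq_along(miss)) assign(miss[[i]], vals[[i]], envir = .canon_cache)
  }
  cached <- vapply(keys, get, character(1), envir = .canon_cache)
  out[todo] <- unname(cached[match(x[todo], keys)])
  out
}

#' Test whether SMILES strings are chemically parsable
#'
#' @param smiles Character vector.
#' @return Logical vector; `FALSE` for unparsable, `NA` or empty input.
#' @export
smiles_valid <- function(smiles) {
  !is.na(canonicalize_smiles(smiles))
}

#' Strip atom-map indices from a SMILES string
#'
#' Removes the `:<n>` atom-map suffixes inside bracket atoms
#' (`[CH3:1]` -> `[CH3]`). Bracket simplification is left to
#' [canonicalize_smiles()].
#'
#' @param smiles Character vector (molecule or reaction SMILES).
#' @return Character vector with map indices removed.
#' @export
strip_atom_maps <- function(smiles) {
  gsub(":[0-9]+\\]", "]", smiles)
}

#' Strip stereochemical marks from a SMILES string
#'
#' Removes tetrahedral (`@`, `@@`) and double-bond (`/`, `\`) stereo marks.
#' Re-canonicalize afterwards to compare structures stereo-blind.
#'
#' @param smiles Character vector.
#' @return Character vector without stereo marks.
#' @export
strip_stereo <- function(smiles) {
  gsub("@", "", gsub("[/\\\\]", "", smiles))
}

# hydrogen molecule in either OpenBabel spelling
is_molecular_hydrogen <- function(canonical_smiles) {
  !is.na(canonical_smiles) & canonical_smiles %in% c("[H][H]", "[HH]")
}

#' Load a name-resolution table
#'
#' A name-resolution table carries two exact-match maps: molecule name ->
#' SMILES (names lower-cased and whitespace-trimmed), and variant SMILES ->
#' representative SMILES for species drawn with differing structures (the
#' classic case is a palladium-phosphine catalyst drawn with different
#' numbers of ligands). All values are canonicalized on load, so every value
#' is a fixed point of [canonicalize_smiles()]; the variant map is checked
#' to be idempotent (no value is itself a key mapping elsewhere).
#'
#' @param names_csv Path to a CSV with header `name,smiles`. `NULL` uses the
#'   packaged dictionary.
#' @param catalysts_csv Path to a CSV with header
#'   `variant_smiles,canonical_smiles`. `NULL` uses the packaged table.
#' @return An object of class `name_table`: list with character maps
#'   `name_to_smiles` and `smiles_to_canonical`.
#' @export
name_resolution_table <- function(names_csv = NULL, catalysts_csv = NULL) {
  names_csv <- names_csv %||%
    system.file("extdata", "name_dictionary.csv", package = "rxncurate")
  catalysts_csv <- catalysts_csv %||%
    system.file("extdata", "catalyst_unification.csv", package = "rxncurate")

  nm <- readr::read_csv(names_csv, col_types = readr::cols(.default = "c"))
  if (!all(c("name", "smiles") %in% names(nm))) {
    abort("name dictionary must have columns `name` and `smiles`")
  }
  vals <- canonicalize_smiles(nm$smiles)
  if (anyNA(vals)) {
    abort(paste0("invalid SMILES in name dictionary: ",
                 paste(nm$smiles[is.na(vals)], collapse = ", ")))
  }
  name_map <- setNames(vals, tolower(trimws(nm$name)))

  ct <- readr::read_csv(catalysts_csv, col_types = readr::cols(.default = "c"))
  if (!all(c("variant_smiles", "canonical_smiles") %in% names(ct))) {
    abort("catalyst table must have columns `variant_smiles` and `canonical_smiles`")
  }
  keys <- canonicalize_smiles(ct$variant_smiles)
  reps <- canonicalize_smiles(ct$canonical_smiles)
  if (anyNA(keys) || anyNA(reps)) abort("invalid SMILES in catalyst unification table")
  cat_map <- setNames(reps, keys)
  # idempotence: representatives must not themselves be remapped
  bad <- reps[reps %in% keys & cat_map[reps] != reps]
  if (length(bad)) {
    abort(paste0("catalyst unification is not idempotent for: ",
                 paste(unique(bad), collapse = ", ")))
  }
  structure(list(name_to_smiles = name_map, smiles_to_canonical = cat_map),
            class = "name_table")
}

#' @export
print.name_table <- function(x, ...) {
  cat(sprintf("<name_table> %d names, %d catalyst variants\n",
              length(x$name_to_smiles), length(x$smiles_to_canonical)))
  invisible(x)
}

# name-like heuristic: whitespace, characters outside the SMILES alphabet,
# or a long all-alphabetic token mark a molecule name rather than a SMILES
looks_like_name <- function(x) {
  grepl("\\s", x) |
    grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*~]", x, perl = TRUE) |
    (grepl("^[A-Za-z]+$", x) & nchar(x) >= 4L)
}

#' Resolve raw molecule strings to canonical SMILES
#'
#' Each raw string is either a SMILES or a molecule name. SMILES are
#' sanitized and canonicalized; strings that fail to parse are looked up
#' (case-insensitive, whitespace-trimmed, exact match) in the
#' name-resolution table. Unresolved names are flagged, never guessed.
#'
#' @param raw Character vector of SMILES strings and/or molecule names.
#' @param table A [name_resolution_table()].
#' @return A tibble with columns `raw`, `canonical_smiles` and `resolution`
#'   (`smiles_ok`, `name_resolved`, `unresolved` or `invalid_smiles`).
#' @export
resolve_molecules <- function(raw, table) {
  stopifnot(inherits(table, "name_table"))
  raw <- as.character(raw)
  canon <- canonicalize_smiles(raw)
  res <- ifelse(!is.na(canon), "smiles_ok", NA_character_)
  miss <- is.na(canon)
  if (any(miss)) {
    key <- tolower(trimws(raw[miss]))
    hit <- table$name_to_smiles[key]
    canon[miss] <- unname(hit)
    res[miss] <- ifelse(!is.na(hit), "name_resolved",
                        ifelse(looks_like_name(raw[miss]), "unresolved", "invalid_smiles"))
  }
  tibble(raw = raw, canonical_smiles = canon, resolution = res)
}

#' Unify multiply-represented catalyst SMILES
#'
#' Maps variant canonical SMILES of one species (e.g. a metal complex drawn
#' with different ligand counts) to a single representative via the
#' unification map of a [name_resolution_table()]. Off-table input is
#' returned unchanged; the operation is idempotent.
#'
#' @param smiles Character vector of canonical SMILES.
#' @param table A [name_resolution_table()].
#' @return Character vector of unified canonical SMILES.
#' @export
unify_catalyst <- function(smiles, table) {
  stopifnot(inherits(table, "name_table"))
  hit <- unname(table$smiles_to_canonical[smiles])
  ifelse(is.na(hit), smiles, hit)
}

#' Load a solvent lexicon
#'
#' Reads a plain-text file with one SMILES per line (blank lines and `#`
#' comments ignored), canonicalizes the entries and returns the set of
#' canonical solvent SMILES used to partition spectator molecules into
#' solvents and agents. The packaged default covers ~50 common laboratory
#' solvents; users may supply their own list.
#'
#' @param path Path to the lexicon file, or `NULL` for the packaged default.
#' @return Character vector of canonical SMILES (class `solvent_lexicon`).
#' @export
read_solvent_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "solvents.smi", package = "rxncurate")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort("solvent lexicon is empty")
  canon <- canonicalize_smiles(lines)
  if (anyNA(canon)) {
    abort(paste0("invalid SMILES in solvent lexicon: ",
                 paste(lines[is.na(canon)], collapse = ", ")))
  }
  structure(unique(canon), class = c("solvent_lexicon", "character"))
}

#' Generate random equivalent SMILES
#'
#' Rewrites each molecule as an equivalent, generally non-canonical SMILES
#' by asking OpenBabel to start the string at a randomly chosen atom. Every
#' output canonicalizes back to the same canonical SMILES as its input.
#' Draws from the current RNG state; seed with [withr::with_seed()] for
#' reproducibility.
#'
#' @param smiles Character vector of single-molecule SMILES.
#' @return Character vector of equivalent SMILES (input returned unchanged
#'   when rewriting fails or the molecule has a single atom).
#' @export
random_equivalent_smiles <- function(smiles) {
  n <- length(smiles)
  if (!n) return(character(0))
  n_atoms <- vapply(smiles, function(s) {
    tk <- tryCatch(tokenize_smiles(s), error = function(e) character(0))
    max(1L, sum(is_atom_token(tk)))
  }, integer(1), USE.NAMES = FALSE)
  start <- vapply(n_atoms, function(k) sample.int(k, 1L), integer(1))
  out <- smiles
  if (Sys.which("obabel") == "") {
    warn("obabel executable not found; returning input SMILES unchanged")
    return(out)
  }
  for (idx in unique(start)) {
    sel <- which(start == idx)
    inp <- tempfile(fileext = ".smi")
    writeLines(paste(smiles[sel], paste0("m", sel)), inp)
    res <- tryCatch(
      suppressWarnings(system2("obabel", c(inp, "-osmi", "-xf", idx),
                               stdout = TRUE, stderr = FALSE)),
      error = function(e) character(0)
    )
    unlink(inp)
    res <- res[nzchar(res)]
    if (length(res)) {
      parts <- strsplit(res, "\t", fixed = TRUE)
      got_id <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "", character(1))
      got_smi <- vapply(parts, function(p) p[[1L]], character(1))
      m <- match(paste0("m", sel), got_id)
      ok <- !is.na(m) & nzchar(got_smi[ifelse(is.na(m), 1L, m)])
      out[sel[ok]] <- got_smi[m[ok]]
    }
  }
  out
}
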