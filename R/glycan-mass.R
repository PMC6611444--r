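# Permethylated glycan mass arithmetic.
#
# Residue increments are the standard monoisotopic masses of permethylated
# glycosyl residues (HexA as its methyl ester), with end-group adjustments for
# a free (hemiacetal) reducing end and for a reduced alditol end as produced
# by reductive beta-elimination. All values in Da.

#' Mass constants for permethylated glycans
#'
#' Returns the monoisotopic residue increments (Da) used throughout the
#' package: permethylated Hex, HexNAc, dHex, and methyl-esterified HexA
#' residues, the end-group adjustments for free and reduced (alditol) reducing
#' ends, and the mass of the lithium cation used for adduct m/z values.
#'
#' The reduced-end adjustment exceeds the free-end adjustment by 16.0313 Da
#' (one CH2 plus two H), reflecting ring opening, reduction, and the extra
#' methyl introduced during permethylation of the alditol.
#'
#' @return A list with elements `residues` (named numeric: `hex`, `hexnac`,
#'   `dhex`, `hexa`), `end` (named numeric: `free`, `reduced`), and `lithium`.
#' @examples
#' glycan_constants()$residues
#' @export
glycan_constants <- function() {
  list(
    residues = c(hex = 204.0998, hexnac = 245.1263,
                 dhex = 174.0892, hexa = 218.0790),
    end = c(free = 46.0419, reduced = 62.0732),
    lithium = 7.0160
  )
}

#' Parse a glycan composition string
#'
#' Accepts both the underscore dialect (`"Hex_5_HexNAc_2_"`) and the compact
#' dialect (`"Hex5HexNAc2"`). Recognized residue tokens are the epimer-blind
#' generic names `Hex`, `HexNAc`, `dHex`, and `HexA`; repeated tokens are
#' summed (so `"HexNAc_1_Hex_3_HexNAc_2_"` has three HexNAc total). Epimers
#' (Glc/Gal/Man and so on) have indistinguishable masses and are never
#' distinguished here.
#'
#' @param text Character vector of composition strings.
#' @param end_state `"free"` (hemiacetal reducing end, enzymatically released
#'   N-glycans) or `"reduced"` (alditol, O-glycans released by reductive
#'   beta-elimination). Recycled along `text`.
#' @param glycan_class `"N"` or `"O"`. Recycled along `text`.
#' @param id Optional integer identifier(s) carried through.
#' @return A tibble with one row per input: `id`, `composition` (canonical
#'   underscore form), `hex`, `hexnac`, `dhex`, `hexa`, `end_state`,
#'   `glycan_class`.
#' @examples
#' parse_composition("Hex5HexNAc2", end_state = "free", glycan_class = "N")
#' @export
parse_composition <- function(text, end_state = c("free", "reduced"),
                              glycan_class = c("N", "O"), id = NA_integer_) {
  end_state <- match.arg(end_state)
  glycan_class <- match.arg(glycan_class)
  stopifnot(is.character(text), length(text) >= 1)
  rows <- purrr::map(text, parse_one_composition)
  out <- dplyr::bind_rows(rows)
  out$id <- vctrs_recycle_int(id, nrow(out))
  out$end_state <- end_state
  out$glycan_class <- glycan_class
  out$composition <- composition_string(out)
  out[, c("id", "composition", "hex", "hexnac", "dhex", "hexa",
          "end_state", "glycan_class")]
}

vctrs_recycle_int <- function(x, n) {
  x <- as.integer(x)
  if (length(x) == 1) rep(x, n) else x
}

parse_one_composition <- function(txt) {
  pattern <- "(dHex|HexNAc|HexA|Hex)_?([0-9]+)_?"
  m <- gregexpr(pattern, txt, perl = TRUE)[[1]]
  counts <- c(hex = 0L, hexnac = 0L, dhex = 0L, hexa = 0L)
  consumed <- rep(FALSE, nchar(txt))
  if (m[1] != -1) {
    for (k in seq_along(m)) {
      start <- m[k]
      len <- attr(m, "match.length")[k]
      tok <- substr(txt, start, start + len - 1)
      consumed[start:(start + len - 1)] <- TRUE
      name <- sub("_?([0-9]+)_?$", "", tok)
      mult <- as.integer(gsub("[^0-9]", "", tok))
      key <- c(Hex = "hex", HexNAc = "hexnac", dHex = "dhex", HexA = "hexa")[name]
      counts[[key]] <- counts[[key]] + mult
    }
  }
  if (!all(consumed)) {
    leftover <- paste(strsplit(txt, "")[[1]][!consumed], collapse = "")
    leftover <- gsub("^_+|_+$", "", leftover)
    abort(paste0("unrecognized token(s) in composition '", txt, "': '",
                 leftover, "' (only Hex, HexNAc, dHex, HexA are accepted)"))
  }
  tibble(hex = counts[["hex"]], hexnac = counts[["hexnac"]],
         dhex = counts[["dhex"]], hexa = counts[["hexa"]])
}

#' Canonical composition string
#'
#' Emits the underscore dialect with residues in the order HexA, dHex, Hex,
#' HexNAc, omitting zero counts.
#'
#' @param comp A tibble with columns `hexa`, `dhex`, `hex`, `hexnac`.
#' @return Character vector.
#' @export
composition_string <- function(comp) {
  piece <- function(tok, n) ifelse(n > 0, paste0(tok, "_", n, "_"), "")
  paste0(piece("HexA", comp$hexa), piece("dHex", comp$dhex),
         piece("Hex", comp$hex), piece("HexNAc", comp$hexnac))
}

#' Permethylated monoisotopic mass of a glycan composition
#'
#' Sums permethylated residue increments and adds the end-group adjustment for
#' the composition's reducing-end state.
#'
#' @param comp A composition tibble as returned by [parse_composition()] (or
#'   any data frame with `hex`, `hexnac`, `dhex`, `hexa`, `end_state`).
#' @param constants Mass constants, see [glycan_constants()].
#' @return Numeric vector of masses in Da.
#' @examples
#' permethylated_mass(parse_composition("Hex5HexNAc2", "free", "N"))
#' @export
permethylated_mass <- function(comp, constants = glycan_constants()) {
  counts <- as.matrix(comp[, c("hex", "hexnac", "dhex", "hexa")])
  if (any(rowSums(counts) == 0)) {
    abort("composition has no residues (all counts zero)")
  }
  res <- constants$residues[c("hex", "hexnac", "dhex", "hexa")]
  unname(drop(counts %*% res) + constants$end[comp$end_state])
}

#' Lithiated m/z for a permethylated glycan mass
#'
#' Permethylated glycans are detected as lithium adducts `[M + zLi]^z+`; the
#' electron mass is neglected (well below the 0.1 Da reporting precision).
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param z Positive integer charge state(s).
#' @param constants Mass constants, see [glycan_constants()].
#' @return Numeric m/z; if both `mass` and `z` have length > 1 they must be
#'   the same length.
#' @examples
#' lithiated_mz(1556.7935, z = 2)
#' @export
lithiated_mz <- function(mass, z = 1L, constants = glycan_constants()) {
  if (any(z <= 0) || any(z != as.integer(z))) {
    abort("charge state z must be a positive integer")
  }
  (mass + z * constants$lithium) / z
}

#' Candidate glycan table
#'
#' Loads the packaged candidate list of N- and O-glycan compositions reported
#' for *C. elegans* (29 reduced O-glycans, 49 free-reducing-end N-glycans) and
#' computes the permethylated mass and lithiated m/z for each requested charge
#' state. A user file with the same columns (`id`, `composition`, `subgroup`,
#' `glycan_class`, `end_state`) can be substituted.
#'
#' @param path Path to a candidate TSV; default is the packaged table.
#' @param z Charge states for which to compute candidate m/z columns.
#' @return A tibble with one row per candidate: identifiers, residue counts,
#'   `label` (`"NG_<id>"` / `"OG_<id>"`), `mass`, and one `mz_<z>` column per
#'   charge state, plus `printed_mass`/`observed_mz` reference columns when
#'   present in the file.
#' @examples
#' cands <- glycan_candidates()
#' nrow(cands)
#' @export
glycan_candidates <- function(path = NULL, z = 1:3) {
  path <- path %||% system.file("extdata", "glycan_candidates.tsv",
                                package = "glycorr")
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) {
    warn("candidate table is empty")
    return(tibble())
  }
  needed <- c("id", "composition", "glycan_class", "end_state")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("candidate table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  rows <- purrr::map(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    ok <- tryCatch({
      comp <- parse_composition(r$composition, end_state = r$end_state,
                                glycan_class = r$glycan_class,
                                id = as.integer(r$id))
      comp$subgroup <- if ("subgroup" %in% names(raw)) r$subgroup else NA_character_
      if ("printed_mass" %in% names(raw)) {
        comp$printed_mass <- as.numeric(r$printed_mass)
      }
      if ("observed_mz" %in% names(raw)) {
        comp$observed_mz <- as.numeric(r$observed_mz)
      }
      comp
    }, error = function(e) e)
    if (inherits(ok, "error")) {
      abort(paste0("malformed candidate row ", i, ": ", conditionMessage(ok)))
    }
    ok
  })
  out <- dplyr::bind_rows(rows)
  out$label <- paste0(ifelse(out$glycan_class == "N", "NG_", "OG_"), out$id)
  out$mass <- permethylated_mass(out)
  for (zz in z) out[[paste0("mz_", zz)]] <- lithiated_mz(out$mass, zz)
  out
}
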