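# SDF (MDL V2000) reading/writing, structure normalization, canonical
# structure keys and training-copy detection.
#
# Only the V2000 dialect is supported; V3000 records are rejected. The
# structure key is a canonical, atom-order-invariant string over the
# heavy-atom graph of the normalized largest fragment, computed by iterative
# neighbourhood refinement with individualization on ties. The framework
# treats it as an opaque identifier.

DEFAULT_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                     F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L)
ATOMIC_WEIGHT <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904,
                   I = 126.904, H = 1.008, B = 10.81, Si = 28.085)

# ---- mol-block parsing -----------------------------------------------------

# Parse a V2000 mol block into an internal graph: element vector, bond table
# (a, b, order). Coordinates are retained for round-tripping.
parse_molblock <- function(lines) {
  if (length(lines) < 4L) qstop("mol block too short")
  counts <- lines[4L]
  if (grepl("V3000", counts, fixed = TRUE))
    qstop("V3000 mol blocks are not supported (V2000 only)")
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n_atoms) || is.na(n_bonds))
    qstop("unparseable counts line in mol block")
  if (n_atoms < 1L) qstop("mol block has no atoms")
  if (length(lines) < 4L + n_atoms + n_bonds)
    qstop("mol block truncated")
  atom_lines <- lines[4L + seq_len(n_atoms)]
  elem <- character(n_atoms)
  xyz <- matrix(0, n_atoms, 3L)
  for (i in seq_len(n_atoms)) {
    ln <- atom_lines[i]
    sym <- trimws(substr(ln, 32L, 34L))
    if (sym == "") {  # fallback for loosely formatted writers
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(toks) < 4L) qstop("unparseable atom line %d", i)
      sym <- toks[4L]
    }
    elem[i] <- sym
    xyz[i, ] <- suppressWarnings(as.numeric(c(substr(ln, 1L, 10L),
                                              substr(ln, 11L, 20L),
                                              substr(ln, 21L, 30L))))
  }
  bonds <- matrix(0L, n_bonds, 3L,
                  dimnames = list(NULL, c("a", "b", "order")))
  if (n_bonds > 0L) {
    bond_lines <- lines[4L + n_atoms + seq_len(n_bonds)]
    for (i in seq_len(n_bonds)) {
      ln <- bond_lines[i]
      a <- suppressWarnings(as.integer(substr(ln, 1L, 3L)))
      b <- suppressWarnings(as.integer(substr(ln, 4L, 6L)))
      o <- suppressWarnings(as.integer(substr(ln, 7L, 9L)))
      if (any(is.na(c(a, b, o))) || a < 1L || b < 1L ||
          a > n_atoms || b > n_atoms)
        qstop("unparseable bond line %d", i)
      bonds[i, ] <- c(a, b, o)
    }
  }
  list(elem = elem, xyz = xyz, bonds = bonds,
       header = lines[1:3], n_atoms = n_atoms, n_bonds = n_bonds)
}

# Serialize an internal graph back to a V2000 mol block (character vector).
write_molblock <- function(g) {
  n_atoms <- length(g$elem); n_bonds <- nrow(g$bonds)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    n_atoms, n_bonds)
  atom_lines <- vapply(seq_len(n_atoms), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            g$xyz[i, 1], g$xyz[i, 2], g$xyz[i, 3], g$elem[i])
  }, character(1))
  bond_lines <- if (n_bonds > 0L)
    vapply(seq_len(n_bonds), function(i)
      sprintf("%3d%3d%3d  0", g$bonds[i, 1], g$bonds[i, 2], g$bonds[i, 3]),
      character(1)) else character(0)
  c(g$header, counts, atom_lines, bond_lines, "M  END")
}

mol_adjacency <- function(g) {
  n <- length(g$elem)
  adj <- vector("list", n)
  ord <- vector("list", n)
  if (nrow(g$bonds) > 0L) for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds[i, 1]; b <- g$bonds[i, 2]; o <- g$bonds[i, 3]
    adj[[a]] <- c(adj[[a]], b); ord[[a]] <- c(ord[[a]], o)
    adj[[b]] <- c(adj[[b]], a); ord[[b]] <- c(ord[[b]], o)
  }
  list(adj = adj, ord = ord)
}

mol_components <- function(g) {
  n <- length(g$elem)
  comp <- rep(0L, n)
  nb <- mol_adjacency(g)$adj
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cid
      stack <- c(stack, nb[[v]][comp[nb[[v]]] == 0L])
    }
  }
  comp
}

# Keep only the atoms in `keep` (logical or index), renumbering bonds.
mol_subset <- function(g, keep) {
  idx <- if (is.logical(keep)) which(keep) else keep
  map <- integer(length(g$elem)); map[idx] <- seq_along(idx)
  bonds <- g$bonds[g$bonds[, 1] %in% idx & g$bonds[, 2] %in% idx, ,
                   drop = FALSE]
  bonds[, 1] <- map[bonds[, 1]]; bonds[, 2] <- map[bonds[, 2]]
  list(elem = g$elem[idx], xyz = g$xyz[idx, , drop = FALSE], bonds = bonds,
       header = g$header, n_atoms = length(idx), n_bonds = nrow(bonds))
}

# ---- canonical structure key ----------------------------------------------

# Iterative refinement: partition atoms by (element, degree, bond-order
# multiset), refine by neighbour classes until stable; resolve remaining
# ties by individualization, taking the lexicographically smallest canonical
# adjacency string over the tried branches.
canonical_key <- function(g) {
  n <- length(g$elem)
  nbx <- mol_adjacency(g)
  init <- vapply(seq_len(n), function(i)
    paste0(g$elem[i], "|", length(nbx$adj[[i]]), "|",
           paste(sort(nbx$ord[[i]]), collapse = ",")), character(1))
  refine <- function(codes) {
    repeat {
      nc <- vapply(seq_len(n), function(i) {
        nb_codes <- sort(paste0(nbx$ord[[i]], ":", codes[nbx$adj[[i]]]))
        paste0(codes[i], "(", paste(nb_codes, collapse = ";"), ")")
      }, character(1))
      new_codes <- as.character(match(nc, sort(unique(nc))))
      if (length(unique(new_codes)) == length(unique(codes)) &&
          identical(as.integer(factor(new_codes, unique(new_codes))),
                    as.integer(factor(codes, unique(codes)))))
        return(codes)
      codes <- new_codes
    }
  }
  # combine the initial invariant with the refined class so element identity
  # survives the renumbering
  base <- refine(init)
  codes0 <- paste0(init, "#", base)
  codes0 <- refine(codes0)

  label_string <- function(perm) {
    # perm: canonical order of atoms; emit elements + sorted bond list
    pos <- integer(n); pos[perm] <- seq_len(n)
    bonds <- g$bonds
    if (nrow(bonds) > 0L) {
      a <- pmin(pos[bonds[, 1]], pos[bonds[, 2]])
      b <- pmax(pos[bonds[, 1]], pos[bonds[, 2]])
      bs <- paste0(a, "-", b, ":", bonds[, 3])
      bs <- bs[order(a, b)]
    } else bs <- character(0)
    paste0(paste(g$elem[perm], collapse = "."), "/",
           paste(bs, collapse = ","))
  }

  best <- NULL
  search <- function(codes, depth) {
    ranks <- rank(match(codes, sort(unique(codes))), ties.method = "min")
    if (anyDuplicated(ranks) == 0L) {
      s <- label_string(order(ranks))
      if (is.null(best) || s < best) best <<- s
      return(invisible())
    }
    if (depth > 12L) {
      # symmetry too deep to enumerate exhaustively; break ties arbitrarily
      # but deterministically by current rank then index
      s <- label_string(order(ranks, seq_along(ranks)))
      if (is.null(best) || s < best) best <<- s
      return(invisible())
    }
    # individualize each atom of the first (smallest) tied cell
    tied_ranks <- sort(unique(ranks[duplicated(ranks) |
                                      duplicated(ranks, fromLast = TRUE)]))
    cell <- which(ranks == tied_ranks[1])
    for (v in cell) {
      codes2 <- codes
      codes2[v] <- paste0(codes2[v], "!")
      search(refine(codes2), depth + 1L)
    }
  }
  search(codes0, 0L)
  paste0("K", n, "b", nrow(g$bonds), "/", best)
}

# ---- SDF record handling ---------------------------------------------------

new_molecule_record <- function(mol_text, name, extra_fields) {
  structure(list(mol_text = mol_text, name = name,
                 activity_raw = NA_character_,
                 extra_fields = extra_fields,
                 structure_key = NA_character_),
            class = "MoleculeRecord")
}

# Split SDF text lines into records at `$$$$`; parse data fields.
parse_sdf_records <- function(lines) {
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0L) qstop("no '$$$$' record separator found")
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- list()
  for (r in seq_along(ends)) {
    rl <- lines[starts[r]:(ends[r] - 1L)]
    if (all(trimws(rl) == "")) next
    mend <- which(grepl("^M  END", rl))
    if (length(mend) == 0L) qstop("record %d: no 'M  END' line", r)
    mol_lines <- rl[seq_len(mend[1])]
    rest <- if (mend[1] < length(rl)) rl[(mend[1] + 1L):length(rl)]
            else character(0)
    fields <- list()
    i <- 1L
    while (i <= length(rest)) {
      ln <- rest[i]
      if (grepl("^>", ln)) {
        m <- regmatches(ln, regexec("<([^>]*)>", ln))[[1]]
        fname <- if (length(m) >= 2L) m[2] else trimws(sub("^>", "", ln))
        vals <- character(0)
        i <- i + 1L
        while (i <= length(rest) && trimws(rest[i]) != "") {
          vals <- c(vals, rest[i]); i <- i + 1L
        }
        fields[[fname]] <- paste(vals, collapse = "\n")
      }
      i <- i + 1L
    }
    rec <- new_molecule_record(paste(mol_lines, collapse = "\n"),
                               name = trimws(mol_lines[1]), fields)
    recs[[length(recs) + 1L]] <- rec
  }
  recs
}

#' Read an SDF training series
#'
#' Parses a multi-record MDL V2000 SDFile with an embedded activity data
#' field into a `TrainingSeries`. Qualitative activities are mapped to 0/1
#' via `label_map`.
#'
#' @param path path to the SDF file
#' @param activity_field name of the SDF data field holding the activity
#'   (default `"activity"`)
#' @param activity_type `"quantitative"` or `"qualitative"`
#' @param label_map named character/numeric map from the two qualitative
#'   source labels to 0/1; default `c("0" = 0, "1" = 1)`
#' @return a `TrainingSeries`: list with `records` (list of
#'   `MoleculeRecord`), `activities` (numeric), `activity_field`,
#'   `activity_type`
#' @export
read_sdf <- function(path, activity_field = "activity",
                     activity_type = c("quantitative", "qualitative"),
                     label_map = c("0" = 0, "1" = 1)) {
  activity_type <- match.arg(activity_type)
  if (!file.exists(path)) qstop("SDF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  recs <- parse_sdf_records(lines)
  if (length(recs) == 0L) qstop("no records in %s", path)
  activities <- numeric(length(recs))
  for (i in seq_along(recs)) {
    # validate the mol block early so errors carry the record index
    g <- tryCatch(parse_molblock(strsplit(recs[[i]]$mol_text, "\n")[[1]]),
                  error = function(e)
                    qstop("record %d: %s", i, conditionMessage(e)))
    val <- recs[[i]]$extra_fields[[activity_field]]
    if (is.null(val))
      qstop("activity field missing in record %d", i)
    recs[[i]]$activity_raw <- val
    if (activity_type == "quantitative") {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        qstop("record %d: activity '%s' is not numeric", i, val)
      activities[i] <- num
    } else {
      key <- trimws(val)
      if (!key %in% names(label_map))
        qstop("record %d: qualitative label '%s' not in declared labels {%s}",
              i, key, paste(names(label_map), collapse = ", "))
      activities[i] <- as.numeric(label_map[[key]])
    }
  }
  if (activity_type == "qualitative" &&
      !all(activities %in% c(0, 1)))
    qstop("label map must target {0, 1}")
  structure(list(records = recs, activities = activities,
                 activity_field = activity_field,
                 activity_type = activity_type),
            class = "TrainingSeries")
}

#' Normalize a molecule record
#'
#' Keeps the largest covalently-bonded fragment (salt/solvent stripping),
#' removes explicit hydrogens and computes the canonical structure key.
#' Idempotent.
#'
#' @param record a `MoleculeRecord`
#' @param settings reserved for future options (ignored)
#' @return the normalized `MoleculeRecord` with `structure_key` set
#' @export
normalize_record <- function(record, settings = list()) {
  g <- parse_molblock(strsplit(record$mol_text, "\n")[[1]])
  comp <- mol_components(g)
  sizes <- vapply(seq_len(max(comp)), function(c)
    sum(comp == c & g$elem != "H"), integer(1))
  biggest <- which.max(sizes)  # ties: first component wins
  g <- mol_subset(g, comp == biggest)
  heavy <- g$elem != "H"
  if (!any(heavy)) qstop("empty molecule after fragment selection")
  g <- mol_subset(g, heavy)
  record$mol_text <- paste(write_molblock(g), collapse = "\n")
  record$structure_key <- canonical_key(g)
  record
}

#' Normalize every record of a training series
#' @param series a `TrainingSeries`
#' @param settings passed to [normalize_record()]
#' @return the series with all records normalized
#' @export
normalize_series <- function(series, settings = list()) {
  series$records <- lapply(series$records, normalize_record,
                           settings = settings)
  series
}

#' Locate a query compound in a training series
#'
#' @param query_key canonical structure key of the (normalized) query
#' @param series a normalized `TrainingSeries`
#' @return 1-based index of the first record with an equal structure key, or
#'   `NA_integer_` when absent
#' @export
find_in_training <- function(query_key, series) {
  keys <- vapply(series$records, function(r) r$structure_key, character(1))
  hit <- which(keys == query_key)
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

#' Write prediction results to SDF or CSV
#'
#' SDF output reproduces the query structures with three added data fields
#' (`prediction`, `AD_category`, `CI95`); CSV output has one row per
#' compound with the same columns. Numeric values are printed with full
#' (17 significant digit) precision so a re-read recovers them exactly.
#'
#' @param results a data.frame of prediction results (see
#'   [predict_workflow()]) with a `mol_text` attribute when SDF output is
#'   requested
#' @param format `"csv"` or `"sdf"`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_predictions <- function(results, format = c("csv", "sdf"), path) {
  format <- match.arg(format)
  if (NROW(results) == 0L) qstop("no prediction results to write")
  num_or_na <- function(x) ifelse(is.na(x), "NA", fmt_num(x))
  pred_chr <- num_or_na(results$y_pred)
  ad_chr <- ifelse(is.na(results$adan_category), "NA",
                   as.character(results$adan_category))
  ci_chr <- num_or_na(results$ci95)
  if (format == "csv") {
    df <- data.frame(compound_id = results$compound_id,
                     prediction = pred_chr,
                     AD_category = ad_chr,
                     CI95 = ci_chr,
                     is_training_copy = results$is_training_copy,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    mol_texts <- attr(results, "mol_text")
    if (is.null(mol_texts)) qstop("SDF output requires mol_text attribute")
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(NROW(results))) {
      writeLines(mol_texts[[i]], con)
      writeLines(c("> <prediction>", pred_chr[i], "",
                   "> <AD_category>", ad_chr[i], "",
                   "> <CI95>", ci_chr[i], "",
                   "$$$$"), con)
    }
  }
  invisible(path)
}

# Write a TrainingSeries (or arbitrary record list) back to SDF, preserving
# data fields verbatim.
write_sdf <- function(records, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) {
    writeLines(rec$mol_text, con)
    for (fname in names(rec$extra_fields)) {
      writeLines(c(sprintf("> <%s>", fname), rec$extra_fields[[fname]], ""),
                 con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' @export
print.TrainingSeries <- function(x, ...) {
  cat(sprintf("TrainingSeries: %d records, %s activity (field '%s')\n",
              length(x$records), x$activity_type, x$activity_field))
  invisible(x)
}
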