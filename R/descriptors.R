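# Built-in 2D molecular descriptors and the "extract" stage that turns a
# training series into a descriptor matrix plus activity vector.
#
# The built-in block is a self-contained substitute for an external
# descriptor engine: simple constitutional and topological descriptors
# computable from the heavy-atom graph alone. External engines can replace
# it through the stage-override mechanism, keyed by descriptor_set_id.

BUILTIN_DESCRIPTOR_SET_ID <- "builtin-2d-v1"

HALOGENS <- c("F", "Cl", "Br", "I")

builtin_var_names <- function() {
  c("n_C", "n_N", "n_O", "n_S", "n_P", "n_halogen", "n_other",
    "n_heavy", "n_bond_single", "n_bond_double", "n_bond_triple",
    "n_bond_aromatic", "ring_count", "n_aromatic_atoms",
    "hbd", "hba", "mol_weight", "zagreb_m1", "wiener")
}

# Implicit hydrogen count per heavy atom from default valences; aromatic
# bonds (order 4) contribute 1.5 to the bond-order sum.
implicit_h <- function(g) {
  n <- length(g$elem)
  bsum <- numeric(n)
  if (nrow(g$bonds) > 0L) for (i in seq_len(nrow(g$bonds))) {
    o <- g$bonds[i, 3]
    contrib <- if (o == 4L) 1.5 else as.numeric(o)
    bsum[g$bonds[i, 1]] <- bsum[g$bonds[i, 1]] + contrib
    bsum[g$bonds[i, 2]] <- bsum[g$bonds[i, 2]] + contrib
  }
  val <- DEFAULT_VALENCE[g$elem]
  val[is.na(val)] <- 0
  pmax(0, round(as.numeric(val) - bsum))
}

# All-pairs shortest topological distances by BFS (unit edge weights).
topo_distances <- function(g) {
  n <- length(g$elem)
  adj <- mol_adjacency(g)$adj
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L
    queue <- s; head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    D[s, ] <- ifelse(dist < 0L, Inf, dist)
  }
  D
}

#' Compute the built-in descriptor vector for one molecule
#'
#' Constitutional and topological descriptors over the heavy-atom graph:
#' element counts, bond counts by order, ring count (cyclomatic number),
#' aromatic-atom count, hydrogen-bond donor/acceptor counts, approximate
#' molecular weight (implicit hydrogens included), first Zagreb index and
#' Wiener index.
#'
#' @param record a normalized `MoleculeRecord`
#' @return named numeric vector; names equal for every molecule
#' @export
compute_builtin <- function(record) {
  g <- parse_molblock(strsplit(record$mol_text, "\n")[[1]])
  if (max(mol_components(g)) > 1L)
    qstop("disconnected molecule: normalize before computing descriptors")
  elem <- g$elem
  known <- c("C", "N", "O", "S", "P", HALOGENS)
  deg <- integer(length(elem))
  arom_atom <- rep(FALSE, length(elem))
  bond_counts <- c(`1` = 0L, `2` = 0L, `3` = 0L, `4` = 0L)
  if (nrow(g$bonds) > 0L) {
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds[i, 1]; b <- g$bonds[i, 2]; o <- g$bonds[i, 3]
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      key <- as.character(min(o, 4L))
      if (key %in% names(bond_counts))
        bond_counts[key] <- bond_counts[key] + 1L
      if (o == 4L) arom_atom[c(a, b)] <- TRUE
    }
  }
  nh <- implicit_h(g)
  D <- topo_distances(g)
  finite_D <- D[is.finite(D)]
  wt <- ATOMIC_WEIGHT[elem]
  wt[is.na(wt)] <- 0
  vec <- c(
    sum(elem == "C"), sum(elem == "N"), sum(elem == "O"),
    sum(elem == "S"), sum(elem == "P"), sum(elem %in% HALOGENS),
    sum(!elem %in% known),
    length(elem),
    bond_counts[["1"]], bond_counts[["2"]], bond_counts[["3"]],
    bond_counts[["4"]],
    nrow(g$bonds) - length(elem) + max(mol_components(g)),
    sum(arom_atom),
    sum(elem %in% c("N", "O") & nh >= 1),
    sum(elem %in% c("N", "O")),
    sum(wt) + sum(nh) * ATOMIC_WEIGHT[["H"]],
    sum(deg^2),
    sum(finite_D) / 2
  )
  names(vec) <- builtin_var_names()
  vec
}

#' Extract the descriptor matrix and activity vector from a series
#'
#' Runs the built-in descriptor block on every (normalized) record and
#' optionally appends numeric values of embedded SDF data fields as extra
#' variables.
#'
#' @param series a normalized `TrainingSeries`
#' @param embedded_fields character vector of SDF data-field names to append
#'   as extra variables (must be numeric in every record)
#' @param descriptor_fun descriptor function applied per record (stage
#'   override point); default [compute_builtin()]
#' @param descriptor_set_id identifier recorded on the matrix
#' @return a `DescriptorMatrix`: list with `values` (n x p), `var_names`,
#'   `compound_ids`, `descriptor_set_id`
#' @export
extract_descriptors <- function(series, embedded_fields = character(0),
                                descriptor_fun = compute_builtin,
                                descriptor_set_id = BUILTIN_DESCRIPTOR_SET_ID) {
  n <- length(series$records)
  rows <- vector("list", n)
  for (i in seq_len(n)) rows[[i]] <- descriptor_fun(series$records[[i]])
  p0 <- length(rows[[1]])
  values <- do.call(rbind, rows)
  var_names <- names(rows[[1]])
  if (length(embedded_fields) > 0L) {
    extra <- matrix(NA_real_, n, length(embedded_fields))
    for (j in seq_along(embedded_fields)) {
      f <- embedded_fields[j]
      for (i in seq_len(n)) {
        val <- series$records[[i]]$extra_fields[[f]]
        if (is.null(val))
          qstop("embedded field '%s' missing in record %d", f, i)
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num))
          qstop("embedded field '%s' non-numeric in record %d", f, i)
        extra[i, j] <- num
      }
    }
    values <- cbind(values, extra)
    var_names <- c(var_names, embedded_fields)
  }
  if (anyDuplicated(var_names))
    qstop("duplicate variable names after appending embedded fields")
  if (!all(is.finite(values))) qstop("non-finite descriptor values")
  ids <- vapply(seq_len(n), function(i) {
    nm <- series$records[[i]]$name
    if (nzchar(nm)) nm else sprintf("compound_%d", i)
  }, character(1))
  dimnames(values) <- list(ids, var_names)
  structure(list(values = values, var_names = var_names,
                 compound_ids = ids,
                 descriptor_set_id = descriptor_set_id),
            class = "DescriptorMatrix")
}

#' Align a query descriptor matrix to a model's variable set
#'
#' Reorders/subsets the query columns to the model's retained variables, in
#' model order.
#'
#' @param query a `DescriptorMatrix` computed with the model's descriptor set
#' @param model_var_names the model's full variable-name vector
#' @param model_var_mask logical mask of retained variables (same length)
#' @param model_descriptor_set_id the model's descriptor-set identifier
#' @return numeric matrix, nq x sum(mask), columns in model order
#' @export
align_to_model <- function(query, model_var_names, model_var_mask,
                           model_descriptor_set_id = BUILTIN_DESCRIPTOR_SET_ID) {
  if (!identical(query$descriptor_set_id, model_descriptor_set_id))
    qstop("descriptor set mismatch: query '%s' vs model '%s'",
          query$descriptor_set_id, model_descriptor_set_id)
  keep <- model_var_names[model_var_mask]
  if (length(keep) == 0L) qstop("empty model variable set")
  missing <- setdiff(keep, query$var_names)
  if (length(missing) > 0L)
    qstop("query lacks model variable(s): %s",
          paste(missing, collapse = ", "))
  query$values[, keep, drop = FALSE]
}
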