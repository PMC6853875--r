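# 3D-SPIEs core: single-linkage inter-fragment distances, the
# distance/energy screen, interaction classification, water bridges,
# hot-spot regions, interaction maps and scatter export.
#
# The screen keeps fragment pairs whose single-linkage distance is within
# the cutoff (default 5.4 A, the separation used for the electrostatic
# approximation in FMO) and whose pair interaction energy is attractively
# stronger than the significance threshold (default -3.0 kcal/mol); both
# boundaries are inclusive.

#' 3D-SPIEs screening parameters
#'
#' @param distance_cutoff single-linkage inter-fragment distance cutoff,
#'   Angstrom (default 5.4).
#' @param attractive_threshold significance threshold on the pair
#'   interaction energy, kcal/mol (default -3.0); records with
#'   `pie <= attractive_threshold` are retained.
#' @param include_repulsive retain pairs regardless of energy.
#' @param heavy_atoms_only compute distances over heavy atoms only.
#' @return parameter list of class `spies_params`.
#' @export
spies_params <- function(distance_cutoff = 5.4, attractive_threshold = -3.0,
                         include_repulsive = FALSE,
                         heavy_atoms_only = FALSE) {
  stopifnot(distance_cutoff > 0)
  out <- list(distance_cutoff = distance_cutoff,
              attractive_threshold = attractive_threshold,
              include_repulsive = include_repulsive,
              heavy_atoms_only = heavy_atoms_only)
  class(out) <- "spies_params"
  out
}

frag_coords <- function(plan, structure, heavy_only = FALSE) {
  atoms <- structure$atoms
  keep <- if (heavy_only) !atoms$is_hydrogen else rep(TRUE, nrow(atoms))
  split(seq_len(nrow(atoms))[keep], plan$assignment$fragment[keep])
}

#' Single-linkage distance between two fragments
#'
#' The minimum over all atom pairs of the Euclidean distance between the
#' member atoms of fragments `i` and `j`.
#'
#' @param plan a `spies_plan`.
#' @param structure the matching structure.
#' @param i,j fragment indices (`i != j`).
#' @param heavy_atoms_only ignore hydrogens.
#' @return distance in Angstrom.
#' @export
min_fragment_distance <- function(plan, structure, i, j,
                                  heavy_atoms_only = FALSE) {
  stopifnot(i != j)
  fc <- frag_coords(plan, structure, heavy_atoms_only)
  ai <- fc[[as.character(i)]]; aj <- fc[[as.character(j)]]
  if (is.null(ai) || is.null(aj) || !length(ai) || !length(aj))
    stopf("fragment %d or %d has no atoms", i, j)
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  cross_min_dist(xyz[ai, , drop = FALSE], xyz[aj, , drop = FALSE])
}

#' All fragment pairs within a distance cutoff
#'
#' Sparse table of single-linkage distances: exactly the unordered pairs
#' with minimum distance at or below `cutoff`.  The `"grid"` backend bins
#' atoms into cutoff-sized cells and only compares neighbouring cells; the
#' `"naive"` backend is the literal double loop.  Both yield identical
#' results.
#'
#' @param plan a `spies_plan`.
#' @param structure the matching structure.
#' @param cutoff distance cutoff, Angstrom.
#' @param backend `"grid"` or `"naive"`.
#' @param heavy_atoms_only ignore hydrogens.
#' @return data.frame `(i, j, distance)` with `i < j`, sorted; the cutoff
#'   is stored in `attr(, "cutoff")`.
#' @export
all_pair_distances <- function(plan, structure, cutoff = 5.4,
                               backend = c("grid", "naive"),
                               heavy_atoms_only = FALSE) {
  stopifnot(cutoff > 0)
  backend <- match.arg(backend)
  atoms <- structure$atoms
  keep <- if (heavy_atoms_only) !atoms$is_hydrogen else rep(TRUE, nrow(atoms))
  xyz <- as.matrix(atoms[keep, c("x", "y", "z")])
  frag <- plan$assignment$fragment[keep]
  out <- if (backend == "naive") {
    pair_dist_naive(xyz, frag, cutoff)
  } else {
    pair_dist_grid(xyz, frag, cutoff)
  }
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

pair_dist_naive <- function(xyz, frag, cutoff) {
  ids <- sort(unique(frag))
  idx <- split(seq_along(frag), frag)
  res <- list()
  for (a in seq_along(ids)) {
    for (b in seq_len(a - 1L)) {
      d <- cross_min_dist(xyz[idx[[as.character(ids[a])]], , drop = FALSE],
                          xyz[idx[[as.character(ids[b])]], , drop = FALSE])
      if (d <= cutoff)
        res[[length(res) + 1L]] <- data.frame(i = ids[b], j = ids[a],
                                              distance = d)
    }
  }
  if (!length(res)) return(data.frame(i = integer(), j = integer(),
                                      distance = numeric()))
  do.call(rbind, res)
}

pair_dist_grid <- function(xyz, frag, cutoff) {
  cell <- floor(xyz / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  cells <- split(seq_len(nrow(xyz)), key)
  cell_of <- lapply(cells, function(ix) cell[ix[1], ])
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  # visit each unordered cell pair once: self plus lexicographically
  # positive offsets
  pos <- offsets[offsets$dx > 0 |
                   (offsets$dx == 0 & (offsets$dy > 0 |
                                        (offsets$dy == 0 & offsets$dz > 0))), ]
  fi <- fj <- integer(); dd <- numeric()
  push <- function(ia, ib, self) {
    d <- cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (self) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    if (nrow(hit) == 0L) return()
    a <- frag[ia[hit[, 1]]]; b <- frag[ib[hit[, 2]]]
    ok <- a != b
    fi <<- c(fi, pmin(a[ok], b[ok]))
    fj <<- c(fj, pmax(a[ok], b[ok]))
    dd <<- c(dd, d[hit][ok])
  }
  for (k in seq_along(cells)) {
    push(cells[[k]], cells[[k]], self = TRUE)
    ck <- cell_of[[k]]
    for (o in seq_len(nrow(pos))) {
      nb <- paste(ck[1] + pos$dx[o], ck[2] + pos$dy[o], ck[3] + pos$dz[o])
      ib <- cells[[nb]]
      if (!is.null(ib)) push(cells[[k]], ib, self = FALSE)
    }
  }
  if (!length(fi)) return(data.frame(i = integer(), j = integer(),
                                     distance = numeric()))
  keyp <- paste(fi, fj)
  mins <- tapply(dd, keyp, min)
  parts <- strsplit(names(mins), " ", fixed = TRUE)
  data.frame(i = as.integer(vapply(parts, `[`, "", 1)),
             j = as.integer(vapply(parts, `[`, "", 2)),
             distance = as.numeric(mins))
}

#' Apply the 3D-SPIEs distance/energy screen
#'
#' Keeps pairs with single-linkage distance within the cutoff and pair
#' interaction energy at or below the attractive threshold (both inclusive;
#' `include_repulsive` lifts the energy condition).  Each retained record
#' carries labels, chains, kinds, the distance, the five decomposition
#' terms and the total.
#'
#' @param table a `pie_table`.
#' @param distances sparse distance table from [all_pair_distances()],
#'   computed with a cutoff at least `params$distance_cutoff`.
#' @param plan the `spies_plan` joining fragment indices to labels.
#' @param params a [spies_params()].
#' @return data.frame of retained records (class `spie_records`).
#' @export
spies_filter <- function(table, distances, plan, params = spies_params()) {
  dc <- attr(distances, "cutoff")
  if (!is.null(dc) && dc < params$distance_cutoff)
    stopf("distance table cutoff (%.2f) is below the screening cutoff (%.2f)",
          dc, params$distance_cutoff)
  rec <- table$records
  bad <- rec$frag_j > plan$n_fragments
  if (any(bad)) {
    warnf("%d pair(s) reference fragments absent from the plan; dropped",
          sum(bad))
    rec <- rec[!bad, , drop = FALSE]
  }
  m <- merge(rec, distances, by.x = c("frag_i", "frag_j"),
             by.y = c("i", "j"))
  m$pie <- m$total
  keep <- m$distance <= params$distance_cutoff &
    (params$include_repulsive | m$pie <= params$attractive_threshold)
  m <- m[keep, , drop = FALSE]
  fr <- plan$fragments
  out <- data.frame(
    frag_i = m$frag_i, frag_j = m$frag_j,
    label_i = fr$label[m$frag_i], label_j = fr$label[m$frag_j],
    chain_i = fr$chain[m$frag_i], chain_j = fr$chain[m$frag_j],
    resseq_i = fr$resseq[m$frag_i], resseq_j = fr$resseq[m$frag_j],
    kind_i = fr$kind[m$frag_i], kind_j = fr$kind[m$frag_j],
    distance = m$distance,
    e_es = m$e_es, e_ex = m$e_ex, e_ct_mix = m$e_ct_mix, e_di = m$e_di,
    g_sol = m$g_sol, pie = m$pie,
    stringsAsFactors = FALSE)
  out <- out[order(out$frag_i, out$frag_j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- params
  class(out) <- c("spie_records", class(out))
  out
}

#' Classify retained records as inter-group, intra-group or water-mediated
#'
#' Chains are mapped to molecule groups (e.g. receptor chains to one group,
#' the two antibody chains to another); pairs across groups are
#' `inter_group` (PPI), within a group `intra_group` (non-PPI); any pair
#' touching a water fragment is `water_mediated` (`water_water` when both
#' sides are waters).
#'
#' @param records `spie_records` from [spies_filter()] (or a data.frame
#'   with `chain_i`, `chain_j`, `kind_i`, `kind_j`).
#' @param chain_groups named vector mapping chain id to group id; water
#'   fragments bypass the map.
#' @return `records` with `group_i`, `group_j`, `iclass` columns.
#' @export
classify_pairs <- function(records, chain_groups) {
  wi <- records$kind_i == "water"
  wj <- records$kind_j == "water"
  need <- unique(c(records$chain_i[!wi], records$chain_j[!wj]))
  unmapped <- setdiff(need, names(chain_groups))
  if (length(unmapped))
    stopf("chain(s) not mapped to a group: %s",
          paste(unmapped, collapse = ", "))
  gi <- ifelse(wi, NA_character_,
               as.character(chain_groups[records$chain_i]))
  gj <- ifelse(wj, NA_character_,
               as.character(chain_groups[records$chain_j]))
  records$group_i <- gi
  records$group_j <- gj
  records$iclass <- ifelse(wi & wj, "water_water",
                           ifelse(wi | wj, "water_mediated",
                                  ifelse(gi == gj, "intra_group",
                                         "inter_group")))
  records
}

#' Detect water-bridge interactions
#'
#' A water bridge is a water fragment whose retained water-mediated
#' records attractively connect residues on both sides of an interface:
#' one bridge per (water, partner_a, partner_b) triple with the partners in
#' different groups.  Enumeration is exhaustive over the retained records.
#'
#' @param records classified records from [classify_pairs()].
#' @return data.frame `(water, partner_a, partner_b, group_a, group_b,
#'   pie_a, pie_b)`.
#' @export
detect_water_bridges <- function(records) {
  empty <- data.frame(water = character(), partner_a = character(),
                      partner_b = character(), group_a = character(),
                      group_b = character(), pie_a = numeric(),
                      pie_b = numeric(), stringsAsFactors = FALSE)
  wm <- records[records$iclass == "water_mediated", , drop = FALSE]
  if (nrow(wm) == 0L) return(empty)
  # long form: one row per (water, partner)
  wat_side_i <- wm$kind_i == "water"
  legs <- data.frame(
    water = ifelse(wat_side_i, wm$label_i, wm$label_j),
    partner = ifelse(wat_side_i, wm$label_j, wm$label_i),
    group = ifelse(wat_side_i, wm$group_j, wm$group_i),
    pie = wm$pie, stringsAsFactors = FALSE)
  # duplicate legs (same water, partner, group) collapse to the strongest
  legs <- legs[order(legs$water, legs$group, legs$partner, legs$pie), ]
  legs <- legs[!duplicated(legs[, c("water", "partner", "group")]), ]
  out <- empty
  for (w in unique(legs$water)) {
    lw <- legs[legs$water == w, , drop = FALSE]
    lw <- lw[order(lw$group, lw$partner), , drop = FALSE]
    n <- nrow(lw)
    if (n < 2L) next
    for (a in seq_len(n - 1L)) {
      for (b in seq.int(a + 1L, n)) {
        if (identical(lw$group[a], lw$group[b])) next
        out <- rbind(out, data.frame(
          water = w, partner_a = lw$partner[a], partner_b = lw$partner[b],
          group_a = lw$group[a], group_b = lw$group[b],
          pie_a = lw$pie[a], pie_b = lw$pie[b], stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(out$water, out$partner_a, out$partner_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group interface residues into hot-spot regions
#'
#' Residues of `group` carrying at least one retained inter-group record
#' are sorted by author numbering and split into runs wherever the gap
#' between consecutive members exceeds `gap_tolerance`.
#'
#' @param records classified records.
#' @param group the group whose residues are collected.
#' @param gap_tolerance maximum residue-number gap inside one region
#'   (default 2).
#' @return data.frame `(region, start, end, n_residues, residues,
#'   support)`; `support` counts retained inter-group records touching the
#'   region.
#' @export
hotspot_regions <- function(records, group, gap_tolerance = 2) {
  stopifnot(gap_tolerance >= 0)
  ig <- records[records$iclass == "inter_group", , drop = FALSE]
  empty <- data.frame(region = integer(), start = numeric(), end = numeric(),
                      n_residues = integer(), residues = character(),
                      support = integer(), stringsAsFactors = FALSE)
  if (nrow(ig) == 0L) return(empty)
  rs <- c(ig$resseq_i[ig$group_i == group], ig$resseq_j[ig$group_j == group])
  if (!length(rs)) return(empty)
  resseqs <- sort(unique(rs))
  cuts <- cumsum(c(0, diff(resseqs) > gap_tolerance))
  out <- empty
  for (g in unique(cuts)) {
    members <- resseqs[cuts == g]
    support <- sum((ig$group_i == group & ig$resseq_i %in% members) |
                     (ig$group_j == group & ig$resseq_j %in% members))
    out <- rbind(out, data.frame(
      region = g + 1L, start = min(members), end = max(members),
      n_residues = length(members),
      residues = paste(members, collapse = ","),
      support = support, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Aggregate significant interactions across complexes
#'
#' Builds the residue-by-complex presence matrix behind an interaction
#' map: a cell is `TRUE` when at least one retained inter-group record in
#' that complex involves the target residue and a partner-molecule
#' fragment.  Rows are sorted by residue number; per-row `commonality`
#' counts the complexes hitting the residue.
#'
#' @param record_sets named list of classified record sets, one per
#'   complex, each with the target protein mapped to `target_group`.
#' @param target_group group id of the common target protein.
#' @return object of class `interaction_map`: list with `presence`
#'   (logical matrix), `strongest` (most attractive PIE per cell),
#'   `residues` (data.frame `resseq`, `label`), `complexes`, `commonality`.
#' @export
build_interaction_map <- function(record_sets, target_group) {
  stopifnot(length(record_sets) >= 1, !is.null(names(record_sets)))
  hits <- lapply(record_sets, function(rec) {
    ig <- rec[rec$iclass == "inter_group", , drop = FALSE]
    side_i <- ig$group_i == target_group
    side_j <- ig$group_j == target_group
    data.frame(
      resseq = c(ig$resseq_i[side_i], ig$resseq_j[side_j]),
      label = c(ig$label_i[side_i], ig$label_j[side_j]),
      pie = c(ig$pie[side_i], ig$pie[side_j]),
      stringsAsFactors = FALSE)
  })
  all_hits <- do.call(rbind, hits)
  # label consistency: a target residue number must carry one label
  lab_of <- unique(all_hits[, c("resseq", "label")])
  dup <- lab_of$resseq[duplicated(lab_of$resseq)]
  if (length(dup))
    stopf("inconsistent target residue labels across complexes for resseq: %s",
          paste(sort(unique(dup)), collapse = ", "))
  lab_of <- lab_of[order(lab_of$resseq), , drop = FALSE]
  rownames(lab_of) <- NULL
  cx <- names(record_sets)
  presence <- matrix(FALSE, nrow(lab_of), length(cx),
                     dimnames = list(lab_of$label, cx))
  strongest <- matrix(NA_real_, nrow(lab_of), length(cx),
                      dimnames = list(lab_of$label, cx))
  for (k in seq_along(cx)) {
    h <- hits[[k]]
    if (nrow(h) == 0L) next
    for (r in seq_len(nrow(lab_of))) {
      sel <- h$resseq == lab_of$resseq[r]
      if (any(sel)) {
        presence[r, k] <- TRUE
        strongest[r, k] <- min(h$pie[sel])
      }
    }
  }
  out <- list(presence = presence, strongest = strongest,
              residues = lab_of, complexes = cx,
              commonality = rowSums(presence))
  class(out) <- "interaction_map"
  out
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("<interaction_map> %d target residues x %d complexes\n",
              nrow(x$presence), ncol(x$presence)))
  disp <- ifelse(x$presence, "x", ".")
  disp <- cbind(disp, commonality = x$commonality)
  print(as.data.frame(disp), ...)
  invisible(x)
}

#' Export retained records as 3D scatter plot records
#'
#' One plot record per retained pair: `x` and `y` are the fragment labels,
#' `z` the single-linkage distance, `value` the pair interaction energy,
#' and the five decomposition terms ride along for hover text.  Serialized
#' as JSON when `path` is given; any HTML rendering is left to the caller
#' and does not affect the JSON.
#'
#' @param records `spie_records` (classified or not).
#' @param path optional JSON output path.
#' @return data.frame of plot records (invisibly when `path` is given).
#' @export
export_scatter <- function(records, path = NULL) {
  df <- data.frame(
    x = records$label_i %||% character(0),
    y = records$label_j %||% character(0),
    z = records$distance %||% numeric(0),
    value = records$pie %||% numeric(0),
    e_es = records$e_es %||% numeric(0),
    e_ex = records$e_ex %||% numeric(0),
    e_ct_mix = records$e_ct_mix %||% numeric(0),
    e_di = records$e_di %||% numeric(0),
    g_sol = records$g_sol %||% numeric(0),
    stringsAsFactors = FALSE)
  if (!is.null(records$iclass)) df$iclass <- records$iclass
  if (!is.null(path)) {
    writeLines(scatter_json(df), path)
    return(invisible(df))
  }
  df
}

#' JSON serialization of scatter plot records
#' @param scatter data.frame from [export_scatter()].
#' @return JSON string (an array of row objects; `[]` when empty).
#' @export
scatter_json <- function(scatter) {
  as.character(jsonlite::toJSON(scatter, dataframe = "rows", digits = NA,
                                na = "null"))
}

#' Write retained records to CSV
#' @param records `spie_records`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spie_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}
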