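# Shared fixtures and independent brute-force oracles.

# --- hand-written PDB text ---------------------------------------------------

pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     occ = 1, altloc = "", icode = "", het = FALSE,
                     element = NULL) {
  if (is.null(element)) {
    element <- sub("^[0-9]+", "", name)
    element <- if (substr(element, 1, 1) %in% c("H", "D")) "H"
               else substr(element, 1, 1)
  }
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, altloc, resname, chain,
          resseq, icode, x, y, z, occ, 0, element)
}

write_pdb_text <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# three-residue glycine-like toy chain (N, CA, C per residue)
toy3_pdb <- function() {
  ln <- character(); s <- 0
  for (r in 1:3) {
    t <- (r - 1) * 4.28
    s <- s + 1; ln <- c(ln, pdb_line(s, "N", "GLY", "A", r, t, 0, 0))
    s <- s + 1; ln <- c(ln, pdb_line(s, "CA", "GLY", "A", r, t + 1.45, 0, 0))
    s <- s + 1; ln <- c(ln, pdb_line(s, "C", "GLY", "A", r, t + 2.95, 0, 0))
  }
  write_pdb_text(ln)
}

# --- oracles -----------------------------------------------------------------

# exhaustive minimum atom-pair distance between two fragments
oracle_min_dist <- function(plan, structure, i, j) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  ai <- which(plan$assignment$fragment == i)
  aj <- which(plan$assignment$fragment == j)
  best <- Inf
  for (a in ai) for (b in aj) {
    d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
    if (d < best) best <- d
  }
  best
}

# brute-force sparse distance table (double loop over all fragment pairs)
oracle_pair_distances <- function(plan, structure, cutoff) {
  n <- plan$n_fragments
  out <- list()
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    d <- oracle_min_dist(plan, structure, i, j)
    if (d <= cutoff)
      out[[length(out) + 1]] <- data.frame(i = i, j = j, distance = d)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(),
                                      distance = numeric()))
  do.call(rbind, out)
}

# fragment partition check: every atom in exactly one non-empty fragment
oracle_partition_ok <- function(plan, structure) {
  a <- plan$assignment
  nrow(a) == nrow(structure$atoms) &&
    !anyNA(a$fragment) &&
    all(a$fragment >= 1 & a$fragment <= plan$n_fragments) &&
    all(seq_len(plan$n_fragments) %in% a$fragment) &&
    !anyDuplicated(a$serial)
}

# exhaustive water-bridge triple enumeration over classified records
oracle_bridges <- function(records) {
  wm <- records[records$iclass == "water_mediated", , drop = FALSE]
  if (nrow(wm) == 0) return(data.frame())
  wat_i <- wm$kind_i == "water"
  legs <- data.frame(water = ifelse(wat_i, wm$label_i, wm$label_j),
                     partner = ifelse(wat_i, wm$label_j, wm$label_i),
                     group = ifelse(wat_i, wm$group_j, wm$group_i),
                     pie = wm$pie, stringsAsFactors = FALSE)
  out <- list()
  for (a in seq_len(nrow(legs))) for (b in seq_len(nrow(legs))) {
    if (a >= b) next
    if (legs$water[a] != legs$water[b]) next
    if (identical(legs$group[a], legs$group[b])) next
    key <- sort(c(paste(legs$group[a], legs$partner[a]),
                  paste(legs$group[b], legs$partner[b])))
    out[[length(out) + 1]] <- data.frame(
      water = legs$water[a], key_a = key[1], key_b = key[2],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame())
  unique(do.call(rbind, out))
}

# random multi-fragment point-cloud structure: each fragment is one ligand
# residue of k atoms (exercises distance code on arbitrary geometry)
make_point_structure <- function(n_frags, atoms_per_frag, seed,
                                 box = 12) {
  set.seed(seed)
  rows <- list(); s <- 0
  for (f in seq_len(n_frags)) {
    centre <- runif(3, 0, box)
    for (k in seq_len(atoms_per_frag)) {
      s <- s + 1
      p <- centre + rnorm(3, sd = 1.2)
      rows[[s]] <- data.frame(
        serial = s, name = paste0("X", k), element = "C", altloc = "",
        resname = "LIG", chain = "L", resseq = f, icode = "",
        x = p[1], y = p[2], z = p[3], occupancy = 1, het = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  new_structure(do.call(rbind, rows), title = "random point cloud")
}

# minimal hand-built classified record rows for classifier/bridge tests
make_record <- function(label_i, label_j, chain_i, chain_j,
                        kind_i = "residue", kind_j = "residue",
                        resseq_i = NA, resseq_j = NA,
                        distance = 3, pie = -5) {
  num <- function(l) suppressWarnings(as.numeric(gsub("[^0-9]", "", l)))
  data.frame(frag_i = 1, frag_j = 2, label_i = label_i, label_j = label_j,
             chain_i = chain_i, chain_j = chain_j,
             resseq_i = if (is.na(resseq_i)) num(label_i) else resseq_i,
             resseq_j = if (is.na(resseq_j)) num(label_j) else resseq_j,
             kind_i = kind_i, kind_j = kind_j,
             distance = distance, e_es = pie, e_ex = 0, e_ct_mix = 0,
             e_di = 0, g_sol = 0, pie = pie, stringsAsFactors = FALSE)
}

# varied seeded toy-complex specs for property sweeps
sweep_specs <- function(n) {
  lapply(seq_len(n), function(k) {
    nc <- 1 + (k %% 3)
    rpc <- 3 + (k %% 5)
    ds <- if (k %% 4 == 0 && nc >= 2 && rpc >= 3)
      list(list(chain_a = "A", resseq_a = 2, chain_b = "B", resseq_b = 2))
    else list()
    toy_complex_spec(n_chains = nc, residues_per_chain = rpc,
                     inter_chain_gap = 3.5 + (k %% 3),
                     n_waters = k %% 3, disulfides = ds, seed = k)
  })
}
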