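#' Synthetic complex scenario
#'
#' Parameters of the benchmark complex generator. The defaults describe a
#' pair of tightly packed alpha-helical chains whose facing side chains
#' interdigitate, giving a genuinely buried interface, available in both
#' all-atom and C-alpha-only renditions.
#'
#' @param n_chains 2 to 7 chains. For the paired-helix geometry, 2 chains
#'   sit side by side, 3 form a triangle and more fill a hexagonal bundle
#'   around a central chain; in a filled bundle the central chain is
#'   enveloped and the inter-helix interstices are too narrow for the
#'   probe, giving a deeply buried interface.
#' @param length Residues per chain (>= 10).
#' @param packing Initial axis-to-axis distance in Angstrom (> 0). With
#'   `repack = TRUE` (the default in [generate_complex()]) chains starting
#'   in steric overlap are slid apart to van der Waals contact, so a small
#'   value (default 7) yields the tightest sterically valid packing for
#'   any seed; 30 Angstrom separates the chains completely.
#' @param geometry `"paired-helix"` (alpha-helical chains packed side by
#'   side or as a bundle) or `"bead-lattice"` (two chains built as
#'   two-layer slabs of extended strands, stacked face to face with
#'   mutual overhangs so that the contact patch is fully enveloped --
#'   the geometry whose 5-Angstrom-contact residues are genuinely buried).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   scenario and seed.
#' @return `complex_scenario` list.
#' @export
complex_scenario <- function(n_chains = 2L, length = 30L, packing = NULL,
                             geometry = c("paired-helix", "bead-lattice"),
                             seed = 1L) {
  geometry <- match.arg(geometry)
  if (is.null(packing)) packing <- if (geometry == "bead-lattice") 4 else 7
  stopifnot(packing > 0, length >= 10, n_chains %in% 2:7)
  structure(list(n_chains = as.integer(n_chains), length = as.integer(length),
                 packing = packing, geometry = geometry,
                 seed = as.integer(seed)),
            class = "complex_scenario")
}

# heavy side-chain atom counts of the 20 amino acids
SIDE_BEADS <- c(A = 1, R = 7, N = 4, D = 4, C = 2, Q = 5, E = 5, G = 0,
                H = 6, I = 4, L = 4, K = 5, M = 4, F = 7, P = 3, S = 2,
                T = 3, V = 3, W = 10, Y = 8)
BEAD_NAMES <- c("CB", "CG", "CD", "CE", "CZ", "CH", "CI", "CK", "CL", "CM")

# one residue's atoms given CA position and a local frame:
# t = chain direction, u = side-chain (outward) direction, v = t x u
residue_atoms <- function(aa, ca, t, u, v) {
  rad <- vdw_radii()
  pos <- rbind(N = ca - 1.2 * t + 0.5 * v,
               CA = ca,
               C = ca + 1.2 * t + 0.5 * v,
               O = ca + 1.2 * t + 1.4 * v)
  elety <- c("N", "CA", "C", "O")
  element <- c("N", "C", "C", "O")
  k <- SIDE_BEADS[[aa]]
  if (k > 0) {
    # compact side-chain blob: beads spread over a cap around the outward
    # direction, so packing is governed by residue bulk, not a single spike
    cap <- list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(1, 1), c(-1, -1), c(1, -1), c(-1, 1), c(2, 0))
    dist <- c(1.6, 2.2, 2.2, 2.2, 2.2, 2.7, 2.7, 2.7, 2.7, 3.0)
    for (j in seq_len(k)) {
      dirv <- u + 0.6 * (cap[[j]][1] * v + cap[[j]][2] * t)
      dirv <- dirv / sqrt(sum(dirv^2))
      pos <- rbind(pos, ca + dist[j] * dirv)
      elety <- c(elety, BEAD_NAMES[j])
      element <- c(element, "C")
    }
  }
  data.frame(elety = elety, element = element,
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             radius = unname(rad[element]), stringsAsFactors = FALSE)
}

# alpha-helix CA trace along the z axis: radius 2.3 A, 100 deg / 1.5 A rise
helix_trace <- function(n, phase = 0) {
  i <- seq_len(n) - 1
  ang <- phase + i * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
}

build_chain <- function(seq1, trace, axis_xy, tilt = NULL, lattice = FALSE,
                        side_sign = 1) {
  n <- length(seq1)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ca <- trace[i, ]
    tdir <- if (i == 1) trace[2, ] - trace[1, ] else if (i == n)
      trace[n, ] - trace[n - 1, ] else trace[i + 1, ] - trace[i - 1, ]
    tdir <- tdir / sqrt(sum(tdir^2))
    if (lattice) {
      u <- c(0, side_sign * cos((i %% 2) * 0.35), sin((i %% 2) * pi - pi / 2) * 0.3)
      u <- u / sqrt(sum(u^2))
    } else {
      u <- c(ca[1] - axis_xy[1], ca[2] - axis_xy[2], 0)
      u <- u / sqrt(sum(u^2))
    }
    if (!is.null(tilt)) {  # small seeded tilt of the side-chain direction
      u <- u + tilt[i, ]
      u <- u - sum(u * tdir) * tdir
      u <- u / sqrt(sum(u^2))
    }
    v <- c(tdir[2] * u[3] - tdir[3] * u[2],
           tdir[3] * u[1] - tdir[1] * u[3],
           tdir[1] * u[2] - tdir[2] * u[1])
    at <- residue_atoms(seq1[i], ca, tdir, u, v)
    at$resno <- i
    rows[[i]] <- at
  }
  do.call(rbind, rows)
}

#' Generate a benchmark complex with a known interface
#'
#' Builds a deterministic multi-chain complex in an all-atom rendition
#' (simplified residues: four backbone atoms plus one side-chain bead per
#' heavy atom) and the matching C-alpha-only rendition obtained by
#' deleting all non-CA atoms with coordinates unchanged. The ground-truth
#' interface is defined independently of any accessibility computation:
#' a residue is labelled interface when any of its heavy atoms lies within
#' `contact_cutoff` of an atom of another chain.
#'
#' @param scn A [complex_scenario()].
#' @param contact_cutoff Ground-truth heavy-atom contact distance (5 A).
#' @param repack Slide chains apart (in the membrane plane, away from each
#'   other) until the closest inter-chain atom pair is at least `gap`
#'   apart, giving the tightest sterically valid packing. With
#'   `repack = FALSE` a scenario producing steric overlap is an error.
#' @param gap Minimum tolerated inter-chain atom distance in Angstrom.
#' @return List with `all_atom` and `calpha` [coat_structure]s, `truth`
#'   (data.frame `chain`, `resno`, `res_type`, `interface`), and `scenario`.
#' @export
#' @examples
#' gc <- generate_complex(complex_scenario(seed = 7))
#' table(gc$truth$interface)
generate_complex <- function(scn, contact_cutoff = 5.0, repack = TRUE,
                             gap = 1.9) {
  stopifnot(inherits(scn, "complex_scenario"))
  set.seed(scn$seed)
  if (scn$geometry == "bead-lattice" && scn$n_chains != 2)
    stop("the bead-lattice geometry is a two-chain slab sandwich")
  slab_s <- max(3L, as.integer(round(sqrt(scn$length / 6))))
  chains <- LETTERS[seq_len(scn$n_chains)]
  atom <- NULL
  for (ci in seq_along(chains)) {
    n <- if (scn$geometry == "bead-lattice") {
      if (ci == 1) slab_s^2 + (slab_s + 4L)^2 else 2L * (slab_s + 4L)^2
    } else scn$length
    seq1 <- sample(AA1, n, replace = TRUE)
    tilt <- matrix(runif(3 * n, -0.15, 0.15), ncol = 3)
    if (scn$geometry == "paired-helix") {
      # chain 1 central, others on a hexagonal ring around it
      axis_xy <- if (ci == 1) c(0, 0) else
        scn$packing * c(cos((ci - 2) * pi / 3), sin((ci - 2) * pi / 3))
      if (scn$n_chains == 3 && ci == 3)
        axis_xy <- scn$packing * c(cos(pi / 3), sin(pi / 3))
      phase <- runif(1, 0, 2 * pi)
      trace <- helix_trace(n, phase)
      trace[, 1] <- trace[, 1] + axis_xy[1]
      trace[, 2] <- trace[, 2] + axis_xy[2]
      at <- build_chain(seq1, trace, axis_xy, tilt)
    } else {
      at <- build_slab_chain(seq1, role = ci, s = slab_s,
                             packing = scn$packing, tilt = tilt)
    }
    at$chain <- chains[ci]
    at$resid <- AA3[match(seq1[at$resno], AA1)]
    at$res_type <- seq1[at$resno]
    atom <- rbind(atom, at)
  }
  atom$insert <- ""
  atom <- atom[, c("chain", "resno", "insert", "resid", "res_type",
                   "elety", "element", "x", "y", "z", "radius")]

  if (repack) atom <- repack_chains(atom, chains, gap)
  # steric sanity: chains may pack tightly but not interpenetrate
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  for (ci in seq_len(length(chains) - 1)) for (cj in (ci + 1):length(chains)) {
    d2 <- min_sq_dist(xyz[atom$chain == chains[ci], , drop = FALSE],
                      xyz[atom$chain == chains[cj], , drop = FALSE])
    if (d2 < 1.5^2)
      stop("steric overlap between chains ", chains[ci], " and ", chains[cj],
           " (min distance ", round(sqrt(d2), 2), " A)")
  }

  all_atom <- new_structure(atom, source_id = sprintf("synthetic-%d", scn$seed))
  truth <- interface_truth(all_atom, contact_cutoff)
  list(all_atom = all_atom, calpha = make_calpha(all_atom), truth = truth,
       scenario = scn)
}

# two-layer slab chain for the bead-lattice geometry: an interface layer
# of extended strands (blobs facing the partner) backed by a second layer
# sealing its rear; the big chain (role 2) overhangs the small one so the
# small chain's contact patch has no free rim
build_slab_chain <- function(seq1, role, s, packing, tilt,
                             dx = 4.2, dy = 5.0, dz = 3.4) {
  grid <- function(i0, i1, j0, j1, off = 0)
    expand.grid(i = i0:i1, j = j0:j1)[, 1:2] + off
  if (role == 1) {
    g_if <- grid(0, s - 1, 0, s - 1)
    g_bk <- grid(-2, s + 1, -2, s + 1)
    # the overhang ring adjacent to the contact patch points its side
    # chains up, lining the binding pocket like a groove wall; the rest
    # of the backing layer points away
    wall <- (g_bk$i >= -1 & g_bk$i <= s & g_bk$j >= -1 & g_bk$j <= s) &
      !(g_bk$i >= 0 & g_bk$i <= s - 1 & g_bk$j >= 0 & g_bk$j <= s - 1)
    layers <- list(list(g = g_if, z = 0, sign = +1),
                   list(g = g_bk, z = -dz, sign = ifelse(wall, +1, -1)))
  } else {
    g_if <- grid(-2, s + 1, -2, s + 1, off = 0.5)
    layers <- list(list(g = g_if, z = packing, sign = -1),
                   list(g = g_if, z = packing + dz, sign = +1))
  }
  rows <- vector("list", length(seq1))
  r <- 1L
  for (ly in layers) {
    for (k in seq_len(nrow(ly$g))) {
      ca <- c(dx * ly$g$i[k], dy * ly$g$j[k], ly$z)
      tdir <- c(1, 0, 0)
      u <- c(0, 0, if (length(ly$sign) > 1) ly$sign[k] else ly$sign)
      u <- u + tilt[r, ]; u <- u - sum(u * tdir) * tdir
      u <- u / sqrt(sum(u^2))
      v <- c(tdir[2] * u[3] - tdir[3] * u[2],
             tdir[3] * u[1] - tdir[1] * u[3],
             tdir[1] * u[2] - tdir[2] * u[1])
      at <- residue_atoms(seq1[r], ca, tdir, u, v)
      at$resno <- r
      rows[[r]] <- at
      r <- r + 1L
    }
  }
  do.call(rbind, rows)
}

# slide overlapping chains apart (away from each other's centroid) until
# every inter-chain atom pair is at least `gap` apart; deterministic
# greedy relaxation
repack_chains <- function(atom, chains, gap) {
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  idx <- lapply(chains, function(ch) which(atom$chain == ch))
  cen <- function(i) colMeans(xyz[i, , drop = FALSE])
  for (iter in seq_len(600)) {
    moved <- FALSE
    for (ci in seq_len(length(chains) - 1)) for (cj in (ci + 1):length(chains)) {
      d2 <- min_sq_dist(xyz[idx[[ci]], , drop = FALSE],
                        xyz[idx[[cj]], , drop = FALSE])
      if (d2 < gap^2) {
        dirv <- cen(idx[[cj]]) - cen(idx[[ci]])
        nrm <- sqrt(sum(dirv^2))
        dirv <- if (nrm < 1e-9) c(1, 0, 0) else dirv / nrm
        xyz[idx[[cj]], ] <- sweep(xyz[idx[[cj]], , drop = FALSE], 2,
                                  0.15 * dirv, "+")
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  atom$x <- xyz[, 1]; atom$y <- xyz[, 2]; atom$z <- xyz[, 3]
  atom
}

# 5 A heavy-atom inter-chain contact labels, independent of any SASA code
interface_truth <- function(structure, contact_cutoff = 5.0) {
  a <- structure$atom
  xyz <- as.matrix(a[, c("x", "y", "z")])
  key <- res_key(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  lab <- logical(sum(first))
  names(lab) <- key[first]
  cut2 <- contact_cutoff^2
  for (k in which(first)) {
    sel <- key == key[k]
    other <- a$chain != a$chain[k]
    if (any(other))
      lab[key[k]] <- min_sq_dist(xyz[sel, , drop = FALSE],
                                 xyz[other, , drop = FALSE]) <= cut2
  }
  data.frame(chain = a$chain[first], resno = a$resno[first],
             res_type = a$res_type[first], interface = unname(lab),
             stringsAsFactors = FALSE)
}

# extended Gly-X-Gly tripeptide used for reference max ASA
build_tripeptide <- function(aa) {
  seq1 <- c("G", aa, "G")
  trace <- cbind(3.8 * (0:2), 0, 0)
  at <- build_chain(seq1, trace, c(0, 0), lattice = TRUE, side_sign = 1)
  at$chain <- "A"
  at$resid <- AA3[match(seq1[at$resno], AA1)]
  at$res_type <- seq1[at$resno]
  at$insert <- ""
  new_structure(at[, c("chain", "resno", "insert", "resid", "res_type",
                       "elety", "element", "x", "y", "z", "radius")],
                source_id = paste0("tripeptide-", aa))
}

#' Evolution scenario for simulated orthologue families
#'
#' Describes a family of orthologues evolved along a species tree with
#' per-site rate heterogeneity (e.g. interface sites slower) and an
#' overall family rate scale (the radial-layer knob: cargo-proximal
#' families evolve faster than the outer lattice).
#'
#' @param n_taxa Number of species (>= 4) when `tree` is generated.
#' @param n_sites Alignment length.
#' @param tree Optional `phylo` species tree; when `NULL` a pure-birth tree
#'   is generated and rescaled to `tree_depth`.
#' @param tree_depth Mean root-to-tip path length (substitutions/site at
#'   rate 1).
#' @param site_rates Named per-class rate multipliers (> 0).
#' @param site_fractions Named class fractions summing to 1; used to draw
#'   a random class assignment when `site_classes` is not given.
#' @param site_classes Optional explicit per-site class labels (length
#'   `n_sites`, values among `names(site_rates)`), e.g. the interface
#'   partition of a structure chain, so that slow sites coincide with
#'   structural interface positions.
#' @param family_scale Overall family rate scale (> 0).
#' @param shared_tree For [generate_mirror_pair()]: evolve both families on
#'   one tree (TRUE) or on independent trees over the same taxa (FALSE).
#' @param seed Integer seed.
#' @export
evolution_scenario <- function(n_taxa = 16L, n_sites = 300L, tree = NULL,
                               tree_depth = 1.0,
                               site_rates = c(interface = 0.2, surface = 1.0),
                               site_fractions = c(interface = 0.3, surface = 0.7),
                               site_classes = NULL,
                               family_scale = 1.0, shared_tree = TRUE,
                               seed = 1L) {
  site_rates <- unlist(site_rates)          # accept YAML-style lists
  site_fractions <- unlist(site_fractions)
  stopifnot(n_taxa >= 4, all(site_rates > 0), family_scale > 0,
            abs(sum(site_fractions) - 1) < 1e-8,
            identical(names(site_rates), names(site_fractions)))
  if (!is.null(site_classes)) {
    site_classes <- as.character(unlist(site_classes))
    stopifnot(length(site_classes) == n_sites,
              all(site_classes %in% names(site_rates)))
  }
  structure(list(n_taxa = as.integer(n_taxa), n_sites = as.integer(n_sites),
                 tree = tree, tree_depth = tree_depth, site_rates = site_rates,
                 site_fractions = site_fractions, site_classes = site_classes,
                 family_scale = family_scale, shared_tree = isTRUE(shared_tree),
                 seed = as.integer(seed)),
            class = "evolution_scenario")
}

sample_species_tree <- function(n_taxa, depth) {
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
  node_depth <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * depth / mean(node_depth[seq_len(n_taxa)])
  tr
}

# evolve one site's state along a branch: Poisson(rate * b) jumps, each to
# a uniformly chosen different amino acid (equal-exchangeability model)
evolve_states <- function(states, b, rates) {
  nev <- rpois(length(states), b * rates)
  for (i in which(nev > 0)) {
    s <- states[i]
    for (k in seq_len(nev[i])) s <- sample(AA1[AA1 != s], 1)
    states[i] <- s
  }
  states
}

#' Simulate an orthologue family along a species tree
#'
#' Root sequence drawn uniformly over the 20 amino acids; substitutions
#' along each branch follow a Poisson process with per-site rate = site
#' class multiplier x family scale, each substitution replacing the
#' residue by one of the other 19 uniformly (equal-exchangeability
#' 20-state model). Under this model two leaves at total path length d
#' (rate 1) differ at a fraction (19/20)(1 - exp(-(20/19) d)) of sites in
#' expectation. Gapless by construction.
#'
#' @param scn An [evolution_scenario()].
#' @return A [msa()] object with attributes `site_class` (per-site class
#'   labels) and `tree` (the species tree used).
#' @export
simulate_family <- function(scn) {
  stopifnot(inherits(scn, "evolution_scenario"))
  set.seed(scn$seed)
  tree <- if (is.null(scn$tree)) sample_species_tree(scn$n_taxa, scn$tree_depth)
          else scn$tree
  site_class <- if (!is.null(scn$site_classes)) scn$site_classes else
    sample(names(scn$site_rates), scn$n_sites, replace = TRUE,
           prob = scn$site_fractions)
  rates <- unname(scn$site_rates[site_class]) * scn$family_scale

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(AA1, scn$n_sites, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- nrow(ord$edge):1  # preorder: root towards tips
  for (e in edges) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    seqs[[child]] <- evolve_states(seqs[[par]], ord$edge.length[e], rates)
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  names(out) <- tree$tip.label
  m <- msa(out, target = tree$tip.label[1])
  attr(m, "site_class") <- site_class
  attr(m, "tree") <- tree
  m
}

#' Generate a pair of families for mirror-tree analysis
#'
#' With `shared_tree = TRUE` both families evolve on the same species tree
#' with independently drawn substitutions (correlated-evolution pair);
#' with `shared_tree = FALSE` the second family evolves on an
#' independently generated tree over the same taxon labels (unrelated
#' baseline pair).
#'
#' @param scn An [evolution_scenario()].
#' @return List of two [msa()] objects, `a` and `b`.
#' @export
generate_mirror_pair <- function(scn) {
  stopifnot(inherits(scn, "evolution_scenario"))
  set.seed(scn$seed)
  tree_a <- if (is.null(scn$tree)) sample_species_tree(scn$n_taxa, scn$tree_depth)
            else scn$tree
  sa <- scn; sa$tree <- tree_a; sa$seed <- scn$seed + 1000003L
  a <- simulate_family(sa)
  sb <- scn
  if (scn$shared_tree) {
    sb$tree <- tree_a
  } else {
    set.seed(scn$seed + 2000003L)
    tb <- sample_species_tree(scn$n_taxa, scn$tree_depth)
    tb$tip.label <- tree_a$tip.label
    sb$tree <- tb
  }
  sb$seed <- scn$seed + 3000017L
  b <- simulate_family(sb)
  list(a = a, b = b)
}
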