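# SNP-sharing structure of clonal isolates: presence/absence matrix,
# carrier-set partition, and Fitch small parsimony rooted on the ancestor.
#
# The ancestor defines the all-absent root state (SNPs are called relative to
# it), so character changes are polarised gains/losses. Trees are rooted,
# with an explicit stem branch from the ancestor to the most recent common
# ancestor of the evolved strains; a SNP shared by every strain sits on that
# stem. Topologies are represented as newick strings over the strain names.

#' Build a strains-by-loci presence matrix
#'
#' @param calls data.frame with columns strain, chrom, pos, ref, alt (e.g.
#'   pooled [call_genome()] calls, or [truth_by_strain()] output).
#' @param strains optional strain ordering (default: sorted unique strains in
#'   `calls`). Strains without calls get all-FALSE rows.
#' @return a `presence_matrix`: logical matrix, rownames = strains,
#'   colnames = locus keys `"chrom:pos:ref>alt"`, columns sorted by position.
#' @export
presence_matrix <- function(calls, strains = NULL) {
  stopifnot(all(c("strain", "chrom", "pos", "ref", "alt") %in% names(calls)))
  strains <- strains %||% sort(unique(calls$strain))
  key <- sprintf("%s:%d:%s>%s", calls$chrom, calls$pos, calls$ref, calls$alt)
  ord <- order(calls$chrom, calls$pos, calls$alt)
  loci <- unique(key[ord])
  m <- matrix(FALSE, length(strains), length(loci),
              dimnames = list(strains, loci))
  m[cbind(match(calls$strain, strains), match(key, loci))] <- TRUE
  if (any(colSums(m) == 0)) {
    stop("presence matrix has an all-absent locus column", call. = FALSE)
  }
  structure(m, class = c("presence_matrix", class(m)))
}

#' Tabulate loci by carrier set
#'
#' Groups loci by the exact set of strains carrying them; subsets with no
#' loci are omitted. Invariant: counts sum to the number of loci.
#'
#' @param pm a [presence_matrix()].
#' @return data.frame: carriers (comma-joined sorted strain names), n_loci;
#'   sorted by decreasing count.
#' @export
partition_counts <- function(pm) {
  strains <- rownames(pm)
  labs <- apply(pm, 2, function(col) paste(sort(strains[col]), collapse = ","))
  tb <- as.data.frame(table(labs), stringsAsFactors = FALSE)
  names(tb) <- c("carriers", "n_loci")
  tb <- tb[order(-tb$n_loci, tb$carriers), , drop = FALSE]
  rownames(tb) <- NULL
  tb
}

#' Count of loci whose carrier set is exactly `strains`
#' @param partition a [partition_counts()] table.
#' @param strains character vector of strain names.
#' @return integer (0 when the subset is absent).
#' @export
partition_subset <- function(partition, strains) {
  lab <- paste(sort(strains), collapse = ",")
  i <- match(lab, partition$carriers)
  if (is.na(i)) 0L else partition$n_loci[i]
}

# ---- rooted topology handling ---------------------------------------------

# internal tree representation: a leaf is a strain name (character scalar);
# an internal node is list(left, right). The ancestor/root sits above the
# whole structure via the stem branch.

topo_leaf <- function(x) is.character(x)

topo_tips <- function(node) {
  if (topo_leaf(node)) return(node)
  sort(c(topo_tips(node[[1]]), topo_tips(node[[2]])))
}

# canonical newick: children ordered by their sorted tip-set label
topo_newick <- function(node) {
  if (topo_leaf(node)) return(node)
  kids <- list(node[[1]], node[[2]])
  labs <- vapply(kids, function(k) paste(topo_tips(k), collapse = ","), "")
  kids <- kids[order(labs)]
  paste0("(", topo_newick(kids[[1]]), ",", topo_newick(kids[[2]]), ")")
}

topo_from_newick <- function(newick) {
  tr <- ape::read.tree(text = if (grepl(";\\s*$", newick)) newick
                              else paste0(newick, ";"))
  if (is.null(tr)) stop("could not parse newick: ", newick, call. = FALSE)
  build <- function(node) {
    ntip <- length(tr$tip.label)
    if (node <= ntip) return(tr$tip.label[node])
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    if (length(kids) != 2) {
      stop("topology must be rooted and binary", call. = FALSE)
    }
    list(build(kids[1]), build(kids[2]))
  }
  build(length(tr$tip.label) + 1L)
}

#' Enumerate all rooted binary topologies over a set of strains
#'
#' There are (2n-3)!! rooted binary shapes for n tips (15 for four strains).
#' Intended for the exhaustive search in [best_topology()]; refuses more than
#' 7 tips.
#'
#' @param tips character vector of strain names.
#' @return list of canonical newick strings (without trailing `;`).
#' @export
enumerate_topologies <- function(tips) {
  tips <- sort(tips)
  if (length(tips) > 7) {
    stop("exhaustive topology enumeration is limited to 7 strains",
         call. = FALSE)
  }
  if (length(tips) == 1) return(tips)
  grow <- function(trees, tip) {
    out <- list()
    for (tr in trees) {
      # attach above every subtree, and above the current root
      attach_at <- function(node) {
        res <- list(list(node, tip))
        if (!topo_leaf(node)) {
          for (l in attach_at(node[[1]])) res <- c(res, list(list(l, node[[2]])))
          for (r in attach_at(node[[2]])) res <- c(res, list(list(node[[1]], r)))
        }
        res
      }
      out <- c(out, attach_at(tr))
    }
    out
  }
  trees <- list(tips[1])
  for (t in tips[-1]) trees <- grow(trees, t)
  sort(vapply(trees, topo_newick, ""))
}

# flatten a topology into parent/child index arrays for the DP.
# node 0 = ancestor root (stem top). Returns list with: parent (int vector
# over nodes 1..N), tip_node (named: strain -> node id), labels (carrier-set
# label per node), depth (edge count from ancestor).
topo_index <- function(topo) {
  parent <- integer(0); label <- character(0); depth <- integer(0)
  is_tip <- logical(0)
  add <- function(node, par, d) {
    id <- length(parent) + 1L
    parent[id] <<- par
    depth[id] <<- d
    if (topo_leaf(node)) {
      label[id] <<- node
      is_tip[id] <<- TRUE
    } else {
      label[id] <<- paste(topo_tips(node), collapse = ",")
      is_tip[id] <<- FALSE
      add(node[[1]], id, d + 1L)
      add(node[[2]], id, d + 1L)
    }
    id
  }
  add(topo, 0L, 1L)
  # children lists in post-order
  children <- lapply(seq_along(parent), function(i) which(parent == i))
  list(parent = parent, label = label, depth = depth, is_tip = is_tip,
       children = children)
}

#' Fitch parsimony branch change counts on a fixed topology
#'
#' Runs the Fitch small-parsimony dynamic program per locus column with the
#' root fixed to the ancestral all-absent state, then assigns changes to
#' branches. When several minimal reconstructions exist, changes are placed
#' on the branch closest to the root (gains as early as possible),
#' deterministically.
#'
#' @param pm a [presence_matrix()].
#' @param topology newick string over the matrix strains (or a parsed
#'   topology).
#' @return a `clado_tree`: list with `topology` (canonical newick),
#'   `branch_changes` (named integer; names are branch carrier-set labels,
#'   the stem branch being all strains), `total_length`, `n_loci`.
#' @export
fitch_branch_counts <- function(pm, topology) {
  topo <- if (is.character(topology) && length(topology) == 1 &&
              grepl("(", topology, fixed = TRUE)) {
    topo_from_newick(topology)
  } else topology
  tips <- topo_tips(topo)
  if (!setequal(tips, rownames(pm))) {
    stop("topology tips do not match presence-matrix strains", call. = FALSE)
  }
  ix <- topo_index(topo)
  nnode <- length(ix$parent)
  tip_rows <- match(ix$label, rownames(pm))   # NA for internal nodes
  internal <- which(!ix$is_tip)
  post <- rev(seq_len(nnode))                 # preorder ids: reverse = postorder

  # per unique column pattern (<= 2^n), solve once
  pat <- apply(pm, 2, function(col) paste0(as.integer(col), collapse = ""))
  upat <- unique(pat)
  per_branch <- matrix(0L, nnode, length(upat),
                       dimnames = list(ix$label, upat))
  score <- setNames(integer(length(upat)), upat)

  for (p in upat) {
    states <- as.integer(strsplit(p, "")[[1]])  # by pm row order
    # Fitch bottom-up: sets encoded as bitmask (1 = {0}, 2 = {1}, 3 = {0,1})
    set <- integer(nnode)
    for (id in post) {
      if (ix$is_tip[id]) {
        set[id] <- if (states[tip_rows[id]] == 1L) 2L else 1L
      } else {
        kids <- ix$children[[id]]
        inter <- bitwAnd(set[kids[1]], set[kids[2]])
        if (inter > 0L) set[id] <- inter
        else {
          set[id] <- bitwOr(set[kids[1]], set[kids[2]])
          score[p] <- score[p] + 1L
        }
      }
    }
    # account for the stem: ancestor fixed at 0
    stem_change <- !bitwAnd(set[1], 1L)
    total <- score[p] + as.integer(stem_change)
    # exact minimal reconstructions over free internal nodes, changes placed
    # rootward-most among minima (deterministic)
    best <- min_reconstruction(ix, states, tip_rows, total)
    per_branch[, p] <- best
    score[p] <- total
  }

  counts <- table(pat)[upat]
  branch_changes <- as.integer(per_branch %*% as.numeric(counts))
  names(branch_changes) <- ix$label
  total_length <- sum(as.integer(score) * as.integer(counts))
  structure(list(topology = topo_newick(topo),
                 branch_changes = branch_changes,
                 total_length = total_length, n_loci = ncol(pm)),
            class = "clado_tree")
}

# exhaustive minimal reconstruction for one column; returns per-branch 0/1
# change indicators for the reconstruction that places changes rootward-most.
# `target` is the known minimum number of changes (from the Fitch pass).
min_reconstruction <- function(ix, states, tip_rows, target) {
  nnode <- length(ix$parent)
  internal <- which(!ix$is_tip)
  fixed <- integer(nnode)
  fixed[ix$is_tip] <- states[tip_rows[ix$is_tip]]
  k <- length(internal)
  best_changes <- NULL
  best_key <- NULL
  # preorder list of internal nodes for the rootward preference key
  ord <- internal[order(ix$depth[internal], internal)]
  for (mask in 0:(2^k - 1)) {
    assign <- fixed
    assign[internal] <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L)
    par_state <- ifelse(ix$parent == 0L, 0L, assign[pmax(ix$parent, 1L)])
    changes <- as.integer(assign != par_state)
    if (sum(changes) != target) next
    # prefer state 1 at shallow nodes (gains rootward); lexicographic
    key <- paste0(assign[ord], collapse = "")
    if (is.null(best_key) || key > best_key) {
      best_key <- key
      best_changes <- changes
    }
  }
  best_changes
}

#' @export
print.clado_tree <- function(x, ...) {
  cat(sprintf("<clado_tree> %s  (parsimony length %d on %d loci)\n",
              x$topology, x$total_length, x$n_loci))
  for (b in names(x$branch_changes)) {
    if (x$branch_changes[[b]] > 0 || !grepl(",", b)) {
      cat(sprintf("  %-40s %d\n", paste0("{", b, "}"), x$branch_changes[[b]]))
    }
  }
  invisible(x)
}

#' Exhaustive maximum-parsimony topology search
#'
#' Enumerates every rooted binary topology over the matrix strains (up to 7),
#' scores each with [fitch_branch_counts()], and returns the minimum; ties
#' are all reported, sorted by canonical newick.
#'
#' @param pm a [presence_matrix()].
#' @return list with `best` (a `clado_tree`), `ties` (character vector of
#'   co-optimal canonical newicks, including the best), and `scores` (named
#'   integer vector over all enumerated topologies).
#' @export
best_topology <- function(pm) {
  topos <- enumerate_topologies(rownames(pm))
  fits <- lapply(topos, function(tp) fitch_branch_counts(pm, tp))
  scores <- vapply(fits, function(f) f$total_length, 0L)
  names(scores) <- vapply(fits, function(f) f$topology, "")
  minlen <- min(scores)
  ties <- sort(names(scores)[scores == minlen])
  list(best = fits[[which(scores == minlen)[1]]], ties = ties,
       scores = scores)
}

#' Write a clado tree as newick with integer branch lengths
#'
#' Branch lengths carry the per-branch SNP change counts; the stem change
#' count is attached to the root.
#'
#' @param tree a `clado_tree`.
#' @param path output path.
#' @param ancestor_name label for the root/ancestor.
#' @export
write_clado_newick <- function(tree, path, ancestor_name = "ancestor") {
  bc <- tree$branch_changes
  render <- function(node) {
    if (topo_leaf(node)) return(sprintf("%s:%d", node, bc[[node]]))
    lab <- paste(topo_tips(node), collapse = ",")
    kids <- list(node[[1]], node[[2]])
    labs <- vapply(kids, function(k) paste(topo_tips(k), collapse = ","), "")
    kids <- kids[order(labs)]
    sprintf("(%s,%s):%d", render(kids[[1]]), render(kids[[2]]), bc[[lab]])
  }
  topo <- topo_from_newick(tree$topology)
  writeLines(sprintf("(%s)%s;", render(topo), ancestor_name), path)
  invisible(path)
}

#' Plain-text rendering of a clado tree
#' @param tree a `clado_tree`.
#' @param ancestor_name label for the root.
#' @return character vector of lines.
#' @export
render_clado_tree <- function(tree, ancestor_name = "ancestor") {
  bc <- tree$branch_changes
  lines <- character(0)
  walk <- function(node, prefix) {
    lab <- if (topo_leaf(node)) node else paste(topo_tips(node), collapse = ",")
    name <- if (topo_leaf(node)) node else "+"
    lines <<- c(lines, sprintf("%s%s --%d-- %s", prefix,
                               if (nzchar(prefix)) "" else "", bc[[lab]], name))
    if (!topo_leaf(node)) {
      walk(node[[1]], paste0(prefix, "    "))
      walk(node[[2]], paste0(prefix, "    "))
    }
  }
  lines <- c(lines, ancestor_name)
  walk(topo_from_newick(tree$topology), "    ")
  lines
}
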