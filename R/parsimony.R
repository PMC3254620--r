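# Maximum-parsimony engine. Ordered (Wagner) characters are optimized by
# Farris interval dynamic programming (equivalent to Sankoff with linear
# costs on a binary tree); unordered characters by Fitch set operations.
# Both are vectorized across characters, so a tree costs O(n) vector
# operations regardless of matrix width.
#
# Trees are held as undirected edge matrices over node indices: leaves
# 1..n (matching cm$taxa order), internal nodes n+1 .. 2n-2. This is the
# "Topology" plumbing; conversion to ape's phylo happens at the interface
# (see trees.R).

# Precompute leaf encodings. Ordered characters: interval [lo, hi] per
# leaf; ambiguity spans the set; missing spans the alphabet. Unordered:
# bitmask; missing = all bits.
encode_matrix <- function(cm, polymorphism = c("uncertainty",
                                               "polymorphism")) {
  polymorphism <- match.arg(polymorphism)
  n <- length(cm$taxa)
  nc <- ncol(cm$cells)
  ordv <- cm$ordered
  oi <- which(ordv); ui <- which(!ordv)
  lo <- matrix(0L, n, length(oi)); hi <- lo
  mask <- matrix(0L, n, length(ui))
  extra <- 0L
  states_of <- function(s) as.integer(strsplit(s, "")[[1]])
  for (i in seq_len(n)) {
    for (k in seq_along(oi)) {
      s <- cm$cells[i, oi[k]]
      if (s == "?") { lo[i, k] <- 0L; hi[i, k] <- cm$nstates[oi[k]] - 1L }
      else {
        st <- states_of(s)
        lo[i, k] <- min(st); hi[i, k] <- max(st)
        if (polymorphism == "polymorphism" && length(st) > 1)
          extra <- extra + (max(st) - min(st))
      }
    }
    for (k in seq_along(ui)) {
      s <- cm$cells[i, ui[k]]
      if (s == "?") mask[i, k] <- bitwShiftL(1L, cm$nstates[ui[k]]) - 1L
      else {
        st <- states_of(s)
        mask[i, k] <- sum(bitwShiftL(1L, st))
        if (polymorphism == "polymorphism" && length(st) > 1)
          extra <- extra + (length(st) - 1L)
      }
    }
  }
  list(n = n, nc = nc, oi = oi, ui = ui, lo = lo, hi = hi, mask = mask,
       extra_steps = extra)
}

# Length of a (possibly partial) unrooted binary tree given as an edge
# matrix. `leaves` are the taxon indices present. Returns total steps and,
# if per_char, the per-character step vector (in matrix column order).
plength <- function(edges, leaves, enc, per_char = FALSE) {
  root_leaf <- leaves[1]
  if (length(leaves) == 1) {
    tot <- enc$extra_steps
    if (per_char) {
      s <- numeric(enc$nc)
      return(list(total = tot, steps = s))
    }
    return(tot)
  }
  nn <- max(edges)
  # adjacency
  deg <- tabulate(c(edges[, 1], edges[, 2]), nn)
  adj <- matrix(0L, nn, 3)
  cnt <- integer(nn)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    cnt[a] <- cnt[a] + 1L; adj[a, cnt[a]] <- b
    cnt[b] <- cnt[b] + 1L; adj[b, cnt[b]] <- a
  }
  start <- adj[root_leaf, 1]
  # iterative postorder from `start`, parent = root_leaf
  nodes <- integer(nn); parent <- integer(nn)
  stack <- integer(nn); sp <- 1L; stack[1] <- start
  parent[start] <- root_leaf
  npost <- 0L
  order_ <- integer(nn)
  # DFS preorder, then reverse for postorder
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    npost <- npost + 1L; order_[npost] <- v
    for (k in seq_len(cnt[v])) {
      w <- adj[v, k]
      if (w != parent[v]) {
        parent[w] <- v
        sp <- sp + 1L; stack[sp] <- w
      }
    }
  }
  post <- order_[npost:1]

  nord <- ncol(enc$lo); nun <- ncol(enc$mask)
  LO <- matrix(0L, nn, nord); HI <- LO
  MK <- matrix(0L, nn, nun)
  nl <- length(leaves)
  LO[leaves, ] <- enc$lo[leaves, , drop = FALSE]
  HI[leaves, ] <- enc$hi[leaves, , drop = FALSE]
  MK[leaves, ] <- enc$mask[leaves, , drop = FALSE]
  ord_steps <- integer(nord); un_steps <- integer(nun)

  comb_ord <- function(a1, b1, a2, b2) {
    m <- pmax(a1, a2); mm <- pmin(b1, b2)
    gap <- m - mm
    add <- pmax(gap, 0L)
    list(lo = pmin(m, mm), hi = pmax(m, mm), add = add)
  }
  comb_un <- function(s1, s2) {
    i <- bitwAnd(s1, s2)
    z <- i == 0L
    i[z] <- bitwOr(s1[z], s2[z])
    list(s = i, add = as.integer(z))
  }

  for (v in post) {
    if (v <= enc$n) next  # leaf
    ch <- adj[v, seq_len(cnt[v])]
    ch <- ch[ch != parent[v]]
    # internal nodes have exactly 2 children under leaf-rooting
    c1 <- ch[1]; c2 <- ch[2]
    if (nord) {
      r <- comb_ord(LO[c1, ], HI[c1, ], LO[c2, ], HI[c2, ])
      LO[v, ] <- r$lo; HI[v, ] <- r$hi; ord_steps <- ord_steps + r$add
    }
    if (nun) {
      r <- comb_un(MK[c1, ], MK[c2, ])
      MK[v, ] <- r$s; un_steps <- un_steps + r$add
    }
  }
  # fold in the root leaf
  if (nl > 1) {
    if (nord) {
      r <- comb_ord(LO[start, ], HI[start, ], LO[root_leaf, ],
                    HI[root_leaf, ])
      ord_steps <- ord_steps + r$add
    }
    if (nun) {
      r <- comb_un(MK[start, ], MK[root_leaf, ])
      un_steps <- un_steps + r$add
    }
  }
  tot <- sum(ord_steps) + sum(un_steps) + enc$extra_steps
  if (!per_char) return(tot)
  s <- numeric(enc$nc)
  s[enc$oi] <- ord_steps; s[enc$ui] <- un_steps
  list(total = tot, steps = s)
}

#' Parsimony length of a tree on a character matrix
#'
#' Counts the minimum number of state changes the tree requires: cost
#' \eqn{|i - j|} between states of ordered characters, unit cost for
#' unordered ones. Ambiguity sets enter as state sets (unordered) or as
#' the interval spanning the set (ordered); missing cells are
#' unconstrained and contribute no forced cost. Length is invariant to
#' root placement.
#'
#' @param tree an \code{ape} \code{phylo} object, or an edge matrix over
#'   node indices with leaves 1..n in \code{cm$taxa} order.
#' @param cm a \code{\link{character_matrix}} whose taxa all appear as tips.
#' @param per_character also return the per-character step counts.
#' @param polymorphism how to cost multi-state cells: as uncertainty
#'   (cheapest resolution, the default) or as true polymorphism (each
#'   terminal pays the span of its set).
#' @return integer total steps, or (with \code{per_character}) a list with
#'   \code{total} and \code{steps}.
#' @export
tree_length <- function(tree, cm, per_character = FALSE,
                        polymorphism = c("uncertainty", "polymorphism")) {
  enc <- encode_matrix(cm, match.arg(polymorphism))
  if (inherits(tree, "phylo")) tree <- phylo_to_edges(tree, cm$taxa)
  if (max(tree) > 2 * enc$n - 2 || !all(seq_len(enc$n) %in% c(tree)))
    stop("tree does not span the matrix taxa")
  res <- plength(tree, seq_len(enc$n), enc, per_char = per_character)
  if (per_character) res else as.integer(res)
}

#' Per-character step bounds
#'
#' For each character, the minimum number of steps on any tree (m) and the
#' number of steps on the completely unresolved star tree with the best
#' central state (g). These are the ingredients of the ensemble indices:
#' CI = sum(m)/sum(s), RI = (sum(g) - sum(s))/(sum(g) - sum(m)).
#' Ambiguity is resolved favourably in both bounds; characters with no
#' scored taxon are flagged uninformative with m = g = 0.
#'
#' @param cm a \code{\link{character_matrix}}.
#' @return data.frame with columns \code{m}, \code{g}, \code{uninformative}.
#' @export
char_bounds <- function(cm) {
  nc <- ncol(cm$cells)
  m <- integer(nc); g <- integer(nc); uninf <- logical(nc)
  for (j in seq_len(nc)) {
    cells <- cm$cells[, j]
    scored <- cells != "?"
    if (!any(scored)) { uninf[j] <- TRUE; next }
    sets <- lapply(cells[scored], function(s) as.integer(strsplit(s, "")[[1]]))
    amax <- cm$nstates[j] - 1L
    if (cm$ordered[j]) {
      a <- vapply(sets, min, 0L); b <- vapply(sets, max, 0L)
      m[j] <- max(0L, max(a) - min(b))
      g[j] <- min(vapply(0:amax, function(cc)
        sum(pmax(a - cc, 0L) + pmax(cc - b, 0L)), 0L))
    } else {
      # minimum hitting set over the alphabet
      found <- FALSE
      for (k in 1:(amax + 1)) {
        combs <- utils::combn(0:amax, k, simplify = FALSE)
        for (S in combs) {
          if (all(vapply(sets, function(st) any(st %in% S), TRUE))) {
            m[j] <- k - 1L; found <- TRUE; break
          }
        }
        if (found) break
      }
      g[j] <- min(vapply(0:amax, function(cc)
        sum(!vapply(sets, function(st) cc %in% st, TRUE)), 0L))
    }
    uninf[j] <- m[j] == g[j]
  }
  data.frame(m = m, g = g, uninformative = uninf)
}

# Shared recursion for exhaustive enumeration and branch and bound.
# Stepwise leaf insertion in taxon order; at depth k the tree spans
# leaves 1..k with internal nodes n+1 .. n+k-2.
search_trees <- function(cm, bound = FALSE,
                         polymorphism = "uncertainty",
                         collect_trees = TRUE) {
  enc <- encode_matrix(cm, polymorphism)
  n <- enc$n
  if (n < 4) {
    edges <- if (n == 2) matrix(c(1L, 2L), 1) else
      matrix(c(1L, n + 1L, 2L, n + 1L, 3L, n + 1L), ncol = 2, byrow = TRUE)
    pl <- plength(edges, seq_len(n), enc, per_char = TRUE)
    return(list(trees = list(edges), length = pl$total, steps = pl$steps,
                enumerated = 1L))
  }
  best <- Inf
  best_trees <- list()
  enumerated <- 0L

  if (bound) {
    # greedy stepwise-addition tree gives the initial upper bound
    edges <- matrix(c(1L, n + 1L, 2L, n + 1L, 3L, n + 1L), ncol = 2,
                    byrow = TRUE)
    for (k in 4:n) {
      newint <- n + k - 2L
      cand_len <- rep(Inf, nrow(edges))
      for (e in seq_len(nrow(edges))) {
        tr <- insert_leaf(edges, e, k, newint)
        cand_len[e] <- plength(tr, seq_len(k), enc)
      }
      edges <- insert_leaf(edges, which.min(cand_len), k, newint)
    }
    best <- plength(edges, seq_len(n), enc)
    best_trees <- list(edges)
  }

  recurse <- function(edges, k) {
    newint <- n + k - 2L
    for (e in seq_len(nrow(edges))) {
      tr <- insert_leaf(edges, e, k, newint)
      if (k == n) {
        enumerated <<- enumerated + 1L
        len <- plength(tr, seq_len(n), enc)
        if (len < best) {
          best <<- len; best_trees <<- list(tr)
        } else if (len == best && collect_trees) {
          best_trees <<- c(best_trees, list(tr))
        }
      } else {
        if (bound) {
          # when only the minimum length is wanted, equal-length partial
          # trees cannot improve on the incumbent and may be pruned too
          pl <- plength(tr, seq_len(k), enc)
          if (pl > best || (!collect_trees && pl >= best)) next
        }
        recurse(tr, k + 1L)
      }
    }
  }
  base <- matrix(c(1L, n + 1L, 2L, n + 1L, 3L, n + 1L), ncol = 2,
                 byrow = TRUE)
  recurse(base, 4L)
  # deduplicate (the greedy seed tree may be rediscovered)
  key <- vapply(best_trees, function(tr)
    paste(canonical_newick(tr, cm$taxa, cm$outgroup), collapse = ""), "")
  keep <- !duplicated(key)
  best_trees <- best_trees[keep][order(key[keep])]
  pl <- plength(best_trees[[1]], seq_len(n), enc, per_char = TRUE)
  # per-character steps can differ between MP trees; the total cannot
  for (tr in best_trees)
    stopifnot(plength(tr, seq_len(n), enc) == pl$total)
  list(trees = best_trees, length = pl$total, steps = pl$steps,
       enumerated = enumerated)
}

insert_leaf <- function(edges, e, leaf, newint) {
  u <- edges[e, 1]; v <- edges[e, 2]
  edges[e, ] <- c(u, newint)
  rbind(edges, c(newint, v), c(newint, leaf))
}

mp_result <- function(cm, sr, method) {
  cb <- char_bounds(cm)
  s <- sr$steps
  structure(list(cm = cm, trees = sr$trees, method = method,
                 TL = as.integer(sr$length), steps = s,
                 m = cb$m, g = cb$g, uninformative = cb$uninformative,
                 enumerated = sr$enumerated),
            class = "parsimony_result")
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates every unrooted binary topology on the matrix's taxa — there
#' are (2n-5)!! of them — by stepwise leaf insertion, and returns all
#' trees attaining the minimum length together with the ensemble
#' statistics. The enumeration count is exact and reported.
#'
#' @param cm a \code{\link{character_matrix}}.
#' @param ceiling refuse above this many taxa (default 11; the tree count
#'   grows as a double factorial, use \code{\link{branch_and_bound}}
#'   beyond).
#' @param collect_trees keep every minimum-length tree (default). With
#'   \code{FALSE} only one representative MP tree and the minimum length
#'   are returned, which permits much stronger pruning in
#'   \code{\link{branch_and_bound}} when tie sets are large.
#' @param polymorphism see \code{\link{tree_length}}.
#' @return a \code{"parsimony_result"}: MP tree set, TL, per-character
#'   steps and bounds, and the CI/HI/RI/RC statistics via
#'   \code{\link{tree_stats}}.
#' @export
exhaustive_search <- function(cm, ceiling = 11,
                              polymorphism = c("uncertainty",
                                               "polymorphism"),
                              collect_trees = TRUE) {
  stopifnot(inherits(cm, "character_matrix"))
  n <- length(cm$taxa)
  if (n > ceiling)
    stop("exhaustive enumeration refused for ", n, " taxa (ceiling ",
         ceiling, "); use branch_and_bound()")
  sr <- search_trees(cm, bound = FALSE,
                     polymorphism = match.arg(polymorphism),
                     collect_trees = collect_trees)
  mp_result(cm, sr, "exhaustive")
}

#' Branch-and-bound maximum-parsimony search
#'
#' Finds exactly the same MP tree set as \code{\link{exhaustive_search}}
#' (parsimony length can only grow as leaves are added, so partial trees
#' longer than the incumbent are pruned), at a fraction of the
#' enumeration.
#'
#' @inheritParams exhaustive_search
#' @return a \code{"parsimony_result"}.
#' @export
branch_and_bound <- function(cm, polymorphism = c("uncertainty",
                                                  "polymorphism"),
                             collect_trees = TRUE) {
  stopifnot(inherits(cm, "character_matrix"))
  sr <- search_trees(cm, bound = TRUE,
                     polymorphism = match.arg(polymorphism),
                     collect_trees = collect_trees)
  mp_result(cm, sr, "branch-and-bound")
}

#' Ensemble tree statistics of a parsimony result
#'
#' Tree length TL = sum of observed steps s_i; consistency index
#' CI = sum(m_i)/sum(s_i); homoplasy index HI = 1 - CI; retention index
#' RI = (sum(g_i) - sum(s_i)) / (sum(g_i) - sum(m_i)), defined as 1 when
#' sum(g) = sum(m); rescaled consistency RC = CI * RI.
#'
#' @param x a \code{"parsimony_result"}.
#' @param exclude_uninformative drop parsimony-uninformative characters
#'   from the sums (default keeps them, the common software default).
#' @return named list TL, CI, HI, RI, RC.
#' @export
tree_stats <- function(x, exclude_uninformative = FALSE) {
  stopifnot(inherits(x, "parsimony_result"))
  keep <- if (exclude_uninformative) !x$uninformative
          else rep(TRUE, length(x$steps))
  S <- sum(x$steps[keep]); M <- sum(x$m[keep]); G <- sum(x$g[keep])
  CI <- if (S == 0) 1 else M / S
  RI <- if (G == M) 1 else (G - S) / (G - M)
  list(TL = as.integer(x$TL), CI = CI, HI = 1 - CI, RI = RI, RC = CI * RI)
}

#' @export
print.parsimony_result <- function(x, ...) {
  st <- tree_stats(x)
  cat(sprintf("%s search: %d MP tree(s)%s\n", x$method, length(x$trees),
              if (x$enumerated > 0)
                sprintf(" (%d topologies evaluated)", x$enumerated)
              else ""))
  cat(sprintf("TL = %d, CI = %.4f, HI = %.4f, RI = %.4f, RC = %.4f\n",
              st$TL, st$CI, st$HI, st$RI, st$RC))
  invisible(x)
}
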