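# Seeded synthetic-data generators. They emulate the statistical frame the
# analyses assume (multivariate-normal shape groups with published
# means/variances; foot skeletons whose inter-element ratios follow the
# published group distributions; discrete characters evolved on a known
# tree) so every stage of the pipeline is testable without the
# unpublished raw specimen data.

#' Specification of one synthetic unguis group
#'
#' @param group group name (e.g. \code{"ungular"}).
#' @param n number of specimens.
#' @param means,vars named vectors over the shape variables; defaults are
#'   the packaged reference summaries for the ungular and grooming groups
#'   (\code{\link{fixtures}("table5")}). Other groups must supply them.
#' @param rho exchangeable correlation among the drawn variables
#'   (default 0: independent, matching the published marginal-only
#'   summaries).
#' @return a \code{"phalanx_group_spec"} list.
#' @export
phalanx_group_spec <- function(group, n, means = NULL, vars = NULL,
                               rho = 0) {
  if (is.null(means) || is.null(vars)) {
    t5 <- fixtures("table5")
    if (!group %in% c("ungular", "grooming"))
      stop("no packaged summaries for group '", group,
           "'; supply means and vars")
    col <- if (group == "ungular") "ungular" else "grooming"
    means <- stats::setNames(t5[[paste0(col, "_mean")]], t5$variable)
    vars <- stats::setNames(t5[[paste0(col, "_var")]], t5$variable)
  }
  stopifnot(all(vars >= 0), abs(rho) < 1, n >= 0)
  structure(list(group = group, n = n, means = means, vars = vars,
                 rho = rho), class = "phalanx_group_spec")
}

# Truncated-normal sampler whose *realized* mean equals `mean`: the
# location parameter is solved so that the upper truncation at `upper`
# does not bias the target moment.
rtnorm_matched <- function(n, mean, sd, upper = Inf) {
  if (!is.finite(upper) || upper - mean > 6 * sd)
    return(stats::rnorm(n, mean, sd))
  tmean <- function(mu) {
    a <- (upper - mu) / sd
    mu - sd * stats::dnorm(a) / stats::pnorm(a)
  }
  mu <- stats::uniroot(function(m) tmean(m) - mean,
                       lower = mean, upper = mean + 6 * sd,
                       extendInt = "upX")$root
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- stats::rnorm(length(need), mu, sd)
    ok <- cand < upper
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic distal-phalanx measurement table
#'
#' Shape is drawn first, size second: the directly drawn quantities are
#' the six standardized variables BH/GM, BW/GM, TPL/GM, SH14/GM, SW14/GM,
#' SW34/GM, the two ratios VFL/TPL (truncated-normal, never above 1, with
#' the location solved so the target mean is preserved) and SH14/SH34,
#' and the angle FSA. VFL/GM and SH34/GM are derived from the ratios so
#' every record is internally consistent. Raw measurements are recovered
#' by multiplying by a log-normal overall size (GM). Records violating
#' the anatomical invariants are rejected and redrawn (error after 1e4
#' rejections).
#'
#' @param specs a \code{\link{phalanx_group_spec}} or list of them.
#' @param seed integer seed; the output is a deterministic function of
#'   (specs, seed).
#' @param gm_meanlog,gm_sdlog log-normal parameters of the synthetic
#'   geometric mean, in log-mm (defaults give unguals of a few mm, the
#'   scale of small-bodied primates).
#' @return data.frame of phalanx records (see
#'   \code{\link{validate_phalanx}}).
#' @export
gen_phalanx_dataset <- function(specs, seed = 1, gm_meanlog = log(3),
                                gm_sdlog = 0.25) {
  if (inherits(specs, "phalanx_group_spec")) specs <- list(specs)
  set.seed(seed)
  direct <- c("BH_GM", "BW_GM", "TPL_GM", "SH14_GM", "SW14_GM", "SW34_GM",
              "VFL_TPL", "SH14_SH34", "FSA")
  rows <- list()
  for (sp in specs) {
    stopifnot(inherits(sp, "phalanx_group_spec"))
    if (sp$n == 0) next
    missing_v <- setdiff(direct, names(sp$means))
    if (length(missing_v))
      stop("spec for group '", sp$group, "' lacks variable(s) ",
           paste(missing_v, collapse = ", "))
    draw_block <- function(nn) {
      if (sp$rho != 0) {
        sds <- sqrt(sp$vars[direct])
        Sig <- outer(sds, sds) * (sp$rho + diag(1 - sp$rho, length(direct)))
        v <- MASS::mvrnorm(nn, sp$means[direct], Sig)
        # the <=1 bound on VFL/TPL is enforced by rejection in this mode
        matrix(v, nn, dimnames = list(NULL, direct))
      } else {
        v <- sapply(direct, function(nm) {
          if (nm == "VFL_TPL")
            rtnorm_matched(nn, sp$means[nm], sqrt(sp$vars[nm]), upper = 1)
          else stats::rnorm(nn, sp$means[nm], sqrt(sp$vars[nm]))
        })
        matrix(v, nn, dimnames = list(NULL, direct))
      }
    }
    std_of <- function(v) {
      cbind(BH = v[, "BH_GM"], BW = v[, "BW_GM"], TPL = v[, "TPL_GM"],
            SH14 = v[, "SH14_GM"], SW14 = v[, "SW14_GM"],
            SH34 = v[, "SH14_GM"] / v[, "SH14_SH34"],
            SW34 = v[, "SW34_GM"], VFL = v[, "VFL_TPL"] * v[, "TPL_GM"])
    }
    valid_rows <- function(v, std) {
      rowSums(std <= 0) == 0 & v[, "FSA"] > 0 & v[, "FSA"] < 180 &
        std[, "VFL"] <= std[, "TPL"] & std[, "SH14"] < std[, "TPL"] &
        std[, "SH34"] < std[, "TPL"]
    }
    v <- draw_block(sp$n)
    std <- std_of(v)
    ok <- valid_rows(v, std)
    tries <- 0L
    while (any(!ok)) {
      tries <- tries + 1L
      if (tries > 1e4)
        stop("infeasible spec for group '", sp$group, "': 1e4 rejections")
      bad <- which(!ok)
      v[bad, ] <- draw_block(length(bad))
      std[bad, ] <- std_of(v[bad, , drop = FALSE])
      ok[bad] <- valid_rows(v[bad, , drop = FALSE],
                            std[bad, , drop = FALSE])
    }
    gm <- stats::rlnorm(sp$n, gm_meanlog, gm_sdlog)
    raw <- std * gm
    rows[[length(rows) + 1L]] <- data.frame(
      specimen_id = sprintf("%s-%04d", sp$group, seq_len(sp$n)),
      taxon = paste0("synthetic_", sp$group),
      digit = NA_integer_,
      unguis_group = sp$group,
      BH = raw[, "BH"], BW = raw[, "BW"], TPL = raw[, "TPL"],
      SH14 = raw[, "SH14"], SW14 = raw[, "SW14"], SH34 = raw[, "SH34"],
      SW34 = raw[, "SW34"], VFL = raw[, "VFL"],
      FSA = v[, "FSA"],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(specimen_id = character(), taxon = character(),
               digit = integer(), unguis_group = character(),
               BH = numeric(), BW = numeric(), TPL = numeric(),
               SH14 = numeric(), SW14 = numeric(), SH34 = numeric(),
               SW34 = numeric(), VFL = numeric(), FSA = numeric(),
               stringsAsFactors = FALSE)
  validate_phalanx(out)
  out
}

#' Specification of one synthetic foot-proportion group
#'
#' @param group group name (e.g. \code{"prosimian"}, \code{"anthropoid"},
#'   or one of the five ratio groups).
#' @param n number of individuals.
#' @param means,vars named vectors over (a subset of) the six ratios
#'   \code{pp4_mt4, mt1_mt2, mt3_mt4, mt4_mt5, pp2_pp5, pp3_pp4};
#'   defaults come from the packaged two-group and five-group summaries
#'   where the group name matches.
#' @param scale mean mt4 length in mm (sets overall body size).
#' @return a \code{"foot_group_spec"} list.
#' @export
foot_group_spec <- function(group, n, means = NULL, vars = NULL,
                            scale = 25) {
  if (is.null(means) || is.null(vars)) {
    t7 <- fixtures("table7"); t8 <- fixtures("table8")
    means <- c(); vars <- c()
    if (group %in% c("prosimian", "anthropoid")) {
      pre <- if (group == "prosimian") "prosimian" else "anthropoid"
      means <- stats::setNames(t7[[paste0(pre, "_mean")]], t7$ratio)
      vars <- stats::setNames(t7[[paste0(pre, "_var")]], t7$ratio)
      g8 <- if (group == "prosimian") "lemuroids" else "anthropoids"
      means <- c(means, stats::setNames(t8[[paste0(g8, "_mean")]], t8$ratio))
      vars <- c(vars, stats::setNames(t8[[paste0(g8, "_var")]], t8$ratio))
    } else if (group %in% c("lorises", "tarsioids", "galagos",
                            "lemuroids", "anthropoids")) {
      means <- stats::setNames(t8[[paste0(group, "_mean")]], t8$ratio)
      vars <- stats::setNames(t8[[paste0(group, "_var")]], t8$ratio)
    } else stop("no packaged summaries for group '", group,
                "'; supply means and vars")
  }
  stopifnot(all(vars >= 0), n >= 0, scale > 0)
  structure(list(group = group, n = n, means = means, vars = vars,
                 scale = scale), class = "foot_group_spec")
}

# Relative element sizes (to mt4) used to anchor elements that no target
# ratio constrains; taken from the proportions of the articulated fossil
# skeleton, with mild log-normal individual noise.
FOOT_ANCHORS <- c(mt2 = 0.931, pp5 = 0.816, pp1 = 0.583,
                  ip2 = 0.527, ip3 = 0.598, ip5 = 0.551)

#' Generate a synthetic foot element-length table
#'
#' Draws the six target ratios from the group's normal distributions and
#' builds 13 element lengths consistent with them: mt4 sets the size,
#' pp4, mt3, mt5 follow from their mt4 ratios, mt2 and pp5 are anchored
#' relative elements, and mt1, pp2, pp3 follow from their ratios. The
#' remaining elements (pp1, ip2, ip3, ip5) are anchored with individual
#' noise. Ratio distributions of the output therefore match the specs
#' exactly in expectation.
#'
#' @param specs a \code{\link{foot_group_spec}} or list of them.
#' @param seed integer seed.
#' @param noise_sdlog log-sd of the anchored-element individual noise.
#' @return data.frame of foot records with \code{individual_id},
#'   \code{taxon}, group-label columns and the 13 element lengths.
#' @export
gen_foot_dataset <- function(specs, seed = 1, noise_sdlog = 0.03) {
  if (inherits(specs, "foot_group_spec")) specs <- list(specs)
  set.seed(seed)
  need <- c("pp4_mt4", "mt1_mt2", "mt3_mt4", "mt4_mt5", "pp2_pp5",
            "pp3_pp4")
  rows <- list()
  for (sp in specs) {
    stopifnot(inherits(sp, "foot_group_spec"))
    if (sp$n == 0) next
    miss <- setdiff(need, names(sp$means))
    if (length(miss))
      stop("spec for group '", sp$group, "' lacks ratio(s) ",
           paste(miss, collapse = ", "))
    draw_r <- function(nn)
      matrix(stats::rnorm(nn * length(need), rep(sp$means[need], each = nn),
                          rep(sqrt(sp$vars[need]), each = nn)),
             nn, dimnames = list(NULL, need))
    r <- draw_r(sp$n)
    tries <- 0L
    while (any(bad <- rowSums(r <= 0) > 0)) {
      tries <- tries + 1L
      if (tries > 1e4)
        stop("infeasible spec for group '", sp$group, "'")
      r[bad, ] <- draw_r(sum(bad))
    }
    mt4 <- sp$scale * stats::rlnorm(sp$n, 0, noise_sdlog)
    anc <- matrix(stats::rlnorm(sp$n * length(FOOT_ANCHORS), 0,
                                noise_sdlog),
                  sp$n, dimnames = list(NULL, names(FOOT_ANCHORS)))
    anc <- sweep(anc, 2, FOOT_ANCHORS, `*`)
    mt2 <- anc[, "mt2"] * mt4
    pp5 <- anc[, "pp5"] * mt4
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = sprintf("%s-%04d", sp$group, seq_len(sp$n)),
      taxon = paste0("synthetic_", sp$group),
      dfa_group = sp$group, ratio_group = sp$group,
      gradistic_group = sp$group,
      mt1 = r[, "mt1_mt2"] * mt2, mt2 = mt2,
      mt3 = r[, "mt3_mt4"] * mt4, mt4 = mt4,
      mt5 = mt4 / r[, "mt4_mt5"],
      pp1 = anc[, "pp1"] * mt4,
      pp2 = r[, "pp2_pp5"] * pp5,
      pp3 = r[, "pp3_pp4"] * r[, "pp4_mt4"] * mt4,
      pp4 = r[, "pp4_mt4"] * mt4, pp5 = pp5,
      ip2 = anc[, "ip2"] * mt4,
      ip3 = anc[, "ip3"] * mt4,
      ip5 = anc[, "ip5"] * mt4,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(individual_id = character(), taxon = character(),
               dfa_group = character(), ratio_group = character(),
               gradistic_group = character(),
               stringsAsFactors = FALSE)
}

#' Specification of a simulated character-evolution experiment
#'
#' @param ntaxa,nchar matrix dimensions.
#' @param nstates states per character (recycled).
#' @param ordered ordered flag per character (recycled).
#' @param change_prob probability of one state change per tree edge.
#' @param missing_rate,polymorphism_rate per-cell probabilities of a
#'   missing entry and of widening a cell into a two-state set.
#' @return an \code{"evol_spec"} list.
#' @export
evol_spec <- function(ntaxa, nchar, nstates = 3, ordered = TRUE,
                      change_prob = 0.05, missing_rate = 0,
                      polymorphism_rate = 0) {
  stopifnot(ntaxa >= 3, nchar >= 1, all(nstates >= 2),
            change_prob >= 0, change_prob <= 1,
            missing_rate >= 0, missing_rate <= 1,
            polymorphism_rate >= 0, polymorphism_rate <= 1)
  structure(list(ntaxa = ntaxa, nchar = nchar,
                 nstates = rep_len(as.integer(nstates), nchar),
                 ordered = rep_len(as.logical(ordered), nchar),
                 change_prob = change_prob, missing_rate = missing_rate,
                 polymorphism_rate = polymorphism_rate),
            class = "evol_spec")
}

# Random unrooted binary topology over n leaves by random stepwise
# insertion; returns an edge matrix (leaves 1..n, internals n+1..2n-2).
random_topology <- function(n) {
  edges <- matrix(c(1L, n + 1L, 2L, n + 1L, 3L, n + 1L), ncol = 2,
                  byrow = TRUE)
  if (n < 4) return(edges)
  for (k in 4:n)
    edges <- insert_leaf(edges, sample.int(nrow(edges), 1), k,
                         as.integer(n + k - 2))
  edges
}

#' Evolve a discrete character matrix on a random tree
#'
#' Simulates a random unrooted binary topology, then evolves each
#' character along it: the root (an arbitrary leaf-adjacent node) starts
#' at the middle state, and on each edge a change occurs with the
#' per-edge probability — a single plus/minus-one step for ordered
#' characters (reflecting at the state bounds), a jump to a uniformly
#' chosen different state for unordered ones. Missing cells and
#' two-state polymorphism are injected afterwards at the stated rates.
#'
#' @param spec an \code{\link{evol_spec}}.
#' @param seed integer seed.
#' @return list with \code{matrix} (a \code{\link{character_matrix}} with
#'   taxa t1..tn, outgroup t1) and \code{tree} (the generating topology,
#'   as a \code{phylo} rooted on t1).
#' @export
gen_character_matrix <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "evol_spec"))
  set.seed(seed)
  n <- spec$ntaxa
  edges <- random_topology(n)
  taxa <- paste0("t", seq_len(n))
  nn <- max(edges)
  adj <- vector("list", nn)
  for (r in seq_len(nrow(edges))) {
    adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], edges[r, 2])
    adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], edges[r, 1])
  }
  cells <- matrix("?", n, spec$nchar)
  for (j in seq_len(spec$nchar)) {
    k <- spec$nstates[j]
    state <- integer(nn)
    root <- adj[[1]][1]
    state[root] <- k %/% 2L
    # BFS away from root
    queue <- root; parent <- integer(nn); parent[root] <- -1L
    head <- 1L
    order_ <- integer(0)
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order_ <- c(order_, v)
      for (w in adj[[v]]) if (w != parent[v] && parent[w] == 0L) {
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
    for (v in order_) {
      if (v == root) next
      s <- state[parent[v]]
      if (stats::runif(1) < spec$change_prob) {
        if (spec$ordered[j]) {
          step <- if (s == 0L) 1L else if (s == k - 1L) -1L else
            sample(c(-1L, 1L), 1)
          s <- s + step
        } else {
          s <- sample(setdiff(0:(k - 1L), s), 1)
        }
      }
      state[v] <- s
    }
    col <- as.character(state[seq_len(n)])
    # polymorphism widening: add an adjacent (ordered) or random other
    # (unordered) state
    wide <- stats::runif(n) < spec$polymorphism_rate
    for (i in which(wide)) {
      s <- as.integer(col[i])
      extra <- if (spec$ordered[j]) {
        if (s == 0L) 1L else if (s == k - 1L) s - 1L else
          s + sample(c(-1L, 1L), 1)
      } else sample(setdiff(0:(k - 1L), s), 1)
      col[i] <- paste(sort(unique(c(s, extra))), collapse = "")
    }
    col[stats::runif(n) < spec$missing_rate] <- "?"
    cells[, j] <- col
  }
  rownames(cells) <- taxa
  cm <- character_matrix(cells, ordered = spec$ordered, outgroup = taxa[1],
                         nstates = spec$nstates)
  tree <- ape::read.tree(text = canonical_newick(edges, taxa, taxa[1]))
  list(matrix = cm, tree = tree)
}
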