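#' Template for a synthetic neck musculoskeletal network
#'
#' Describes the composition of a generated neck network: a serial bone
#' backbone (cranium - C1..Cn - thoracic spine, plus girdle articulations),
#' optional skeletal elements, and a blueprint of bilateral muscles with
#' origin and insertion element sets (2-10 bone attachments per muscle).
#' `attachment_noise` is the per-muscle probability that one vertebral
#' attachment is added or dropped when the network is generated, which is
#' what makes replicate networks differ in link count the way real species
#' differ in muscle attachment sites. Fidelity is statistical - the default
#' template lands in the empirically observed ranges of node and link counts
#' (roughly 84-130 nodes, 219-397 links) - not anatomical truth.
#'
#' @param n_cervical Number of cervical vertebrae (5-9; mammals have 7 except
#'   sloths and manatees).
#' @param has_clavicle,has_mandible,has_humerus,has_nuchal_ligament Include
#'   these optional elements?
#' @param attachment_noise Per-muscle probability of one added/dropped
#'   vertebral attachment.
#' @return A list of class `neck_template` with the bone set, joint list and
#'   muscle blueprint.
#' @export
neck_template <- function(n_cervical = 7, has_clavicle = TRUE,
                          has_mandible = TRUE, has_humerus = TRUE,
                          has_nuchal_ligament = TRUE,
                          attachment_noise = 0.15) {
  if (n_cervical < 5 || n_cervical > 9) abort("n_cervical must be in 5..9")
  nc <- n_cervical
  cerv <- paste0("C", seq_len(nc))
  midline <- c("cr", "hy", "ty", "st", "ts", cerv)
  if (has_mandible) midline <- c(midline, "md")
  if (has_nuchal_ligament) midline <- c(midline, "ln")
  bilateral_bones <- c("ri", "sc")
  if (has_clavicle) bilateral_bones <- c(bilateral_bones, "cl")
  if (has_humerus) bilateral_bones <- c(bilateral_bones, "hu")

  joints <- list(c("cr", "C1"))
  for (i in seq_len(nc - 1)) joints <- c(joints, list(c(cerv[i], cerv[i + 1])))
  joints <- c(joints, list(c(cerv[nc], "ts")),
              list(c("ts", "ril")), list(c("ts", "rir")),
              list(c("ril", "st")), list(c("rir", "st")),
              list(c("hy", "ty")))
  if (has_mandible) joints <- c(joints, list(c("cr", "md")))
  if (has_nuchal_ligament) joints <- c(joints, list(c("ln", "cr")),
                                       list(c("ln", "ts")))
  if (has_clavicle) joints <- c(joints, list(c("st", "cll")), list(c("st", "clr")),
                                list(c("cll", "scl")), list(c("clr", "scr")))
  if (has_humerus) joints <- c(joints, list(c("scl", "hul")),
                               list(c("scr", "hur")))

  mid <- function(i) cerv[pmin(pmax(i, 1), nc)]   # clip serial indices
  mus <- function(name, attach, vertebral = character(0)) {
    list(name = name, attach = unique(attach), vertebral = unique(vertebral))
  }
  upper <- cerv[seq_len(min(2, nc))]
  blueprint <- list(
    # suboccipital / capital muscles
    mus("rmi", c("cr", "C1")), mus("rma", c("cr", "C2")),
    mus("oca", c("C1", "C2")), mus("ocr", c("cr", "C1")),
    mus("rl", c("cr", "C1")), mus("rv", c("cr", "C1")),
    # deep serial muscles between successive vertebrae
    mus("is1", mid(2:3), mid(2:3)), mus("is2", mid(3:4), mid(3:4)),
    mus("is3", mid(4:5), mid(4:5)), mus("is4", c(mid((nc - 1):nc), "ts"),
                                        mid((nc - 1):nc)),
    mus("id1", mid(2:3), mid(2:3)), mus("id2", mid(3:4), mid(3:4)),
    mus("id3", mid(5:6), mid(5:6)), mus("id4", c(mid(nc), "ts"), mid(nc)),
    mus("iv", mid(2:nc), mid(2:nc)),
    mus("m1", c(mid(2:4)), mid(2:4)), mus("m2", mid(4:6), mid(4:6)),
    mus("m3", c(mid((nc - 1):nc), "ts"), mid((nc - 1):nc)),
    # prevertebral
    mus("cal", c("cr", mid(3:6)), mid(3:6)),
    mus("col", c(cerv, "ts"), cerv),
    mus("lat", c("C1", mid(3:5)), mid(3:5)),
    # scalenes (to the ribs)
    mus("sd", c("ri", mid(3:5)), mid(3:5)),
    mus("sm", c("ri", mid(4:6)), mid(4:6)),
    mus("sv", c("ri", mid(5:nc)), mid(5:nc)),
    # longissimus / iliocostalis systems
    mus("lca", c("cr", mid(4:nc), "ts"), mid(4:nc)),
    mus("lce", c(mid(4:nc), "ts"), mid(4:nc)),
    mus("icc", c("ri", mid(5:nc)), mid(5:nc)),
    # transversospinal system
    mus("ssca", c("cr", mid(4:nc), "ts"), mid(4:nc)),
    mus("ssce", c(mid(2:5), "ts"), mid(2:5)),
    mus("sce", c(mid(2:4), "ts"), mid(2:4)),
    # splenius group
    mus("spca", c("cr", "ts", if (has_nuchal_ligament) "ln")),
    mus("spce", c(mid(1:3), "ts"), mid(1:3)),
    # ventral strap muscles
    mus("sh", c("st", "hy")), mus("sth", c("st", "ty")),
    mus("oh", c("sc", "hy")),
    mus("scm", c("st", if (has_clavicle) "cl", "cr")),
    mus("so", c("st", "cr")),
    if (has_clavicle) mus("cm", c("cl", "cr")),
    if (has_mandible) mus("stx", c("st", "md")),
    # neck-shoulder muscles
    mus("tr", c("cr", if (has_nuchal_ligament) "ln", "sc",
                if (has_clavicle) "cl", "ts")),
    mus("rca", c("cr", "sc")),
    mus("rce", c(mid(4:nc), "sc", if (has_nuchal_ligament) "ln"), mid(4:nc)),
    mus("asd", c("C1", "sc")),
    mus("svc", c(mid(3:nc), "sc"), mid(3:nc))
  )
  blueprint <- blueprint[!vapply(blueprint, is.null, logical(1))]
  structure(list(n_cervical = nc, cervicals = cerv, midline = midline,
                 bilateral_bones = bilateral_bones, joints = joints,
                 blueprint = blueprint, attachment_noise = attachment_noise),
            class = "neck_template")
}

#' Generate a synthetic neck network
#'
#' Instantiates a [neck_template()] as an [anatomical_network()]: bilateral
#' muscles become mirrored left/right nodes attached to midline bones
#' directly and to bilateral bones of their own side; per-muscle attachment
#' noise adds or drops one vertebral attachment (never below two total
#' attachments, so no muscle is stranded). If noise ever disconnects the
#' graph, the isolated part is reconnected to the cranium with a warning.
#'
#' @param template A [neck_template()].
#' @param seed Integer seed (mandatory).
#' @param species Name for the generated network.
#' @return An [anatomical_network()].
#' @examples
#' net <- generate_network(neck_template(), seed = 1)
#' net
#' @export
generate_network <- function(template = neck_template(), seed,
                             species = sprintf("synthetic_%d", seed)) {
  stopifnot(inherits(template, "neck_template"))
  with_seed_restore(seed, {
    edges <- list()
    for (j in template$joints) edges <- c(edges, list(j))
    nodes <- c(template$midline,
               paste0(template$bilateral_bones, "l"),
               paste0(template$bilateral_bones, "r"))
    for (side in c("l", "r")) {
      for (m in template$blueprint) {
        attach <- m$attach
        # attachment-site noise on the vertebral attachments
        if (length(m$vertebral) > 0 && runif(1) < template$attachment_noise) {
          if (runif(1) < 0.5 && length(attach) > 2) {
            attach <- setdiff(attach, sample(m$vertebral, 1))
          } else {
            pool <- setdiff(template$cervicals, attach)
            if (length(pool) > 0) attach <- c(attach, sample(pool, 1))
          }
        }
        node <- paste0(m$name, side)
        targets <- ifelse(attach %in% template$bilateral_bones,
                          paste0(attach, side), attach)
        edges <- c(edges, lapply(targets, function(tg) c(node, tg)))
        nodes <- c(nodes, node)
      }
    }
    em <- do.call(rbind, edges)
    net <- anatomical_network(species, unique(nodes),
                              tibble(from = em[, 1], to = em[, 2]),
                              validate = FALSE)
    g <- as_igraph(net)
    if (!igraph::is_connected(g)) {
      warn("generated network was disconnected; reattaching isolated parts to the cranium")
      comp <- igraph::components(g)
      main <- which.max(comp$csize)
      stray <- names(comp$membership)[comp$membership != main]
      extra <- tibble(from = stray, to = "cr")
      net <- anatomical_network(species, net$nodes,
                                bind_rows(net$edges, extra), validate = FALSE)
    }
    validate_network(net)
    net
  })
}

#' Generate a calibrated pure-birth tree
#'
#' Yule (pure-birth) tree, ultrametric, rescaled so that all tip depths equal
#' `root_age`. The default root age of 170 time units matches the order of
#' magnitude of the mammalian crown age in millions of years.
#'
#' @param n_tips Number of tips (at least 2).
#' @param seed Integer seed.
#' @param root_age Depth of the rescaled tree.
#' @param tip_prefix Tip labels are `paste0(tip_prefix, 1:n_tips)`.
#' @return An `ape::phylo` tree.
#' @export
generate_tree <- function(n_tips, seed, root_age = 170, tip_prefix = "sp") {
  if (n_tips < 2) abort("need at least 2 tips")
  with_seed_restore(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * root_age / depth
    tree$tip.label <- paste0(tip_prefix, seq_len(n_tips))
    tree
  })
}

#' Simulate traits on a tree
#'
#' Multivariate normal draws over the tips under Brownian motion,
#' single-optimum Ornstein-Uhlenbeck, or early burst, using the same
#' covariance transforms as [fit_evo_models()], so the simulator doubles as
#' the recovery-test generator for the comparative methods.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param seed Integer seed.
#' @param n_traits Number of traits when `rate` is scalar.
#' @param rate BM rate \eqn{\sigma^2}: scalar (independent traits) or a
#'   positive-definite among-trait matrix.
#' @param alpha OU pull strength (required for OU).
#' @param r EB rate-decay exponent, nonpositive (required for EB).
#' @param mean Root state(s), recycled over traits.
#' @return A tibble with a `species` column and one column per trait.
#' @export
simulate_traits <- function(tree, model = c("BM", "OU", "EB"), seed,
                            n_traits = 1, rate = 1, alpha = NULL, r = NULL,
                            mean = 0) {
  model <- match.arg(model)
  if (is.matrix(rate)) n_traits <- ncol(rate) else
    rate <- diag(rate, n_traits, n_traits)
  if (any(diag(rate) < 0)) abort("rate must be nonnegative")
  chol_psd <- function(M) {
    tryCatch(chol(M), error = function(e) {
      ei <- eigen(M, symmetric = TRUE)
      t(ei$vectors %*% diag(sqrt(pmax(ei$values, 0)), nrow(M)) %*% t(ei$vectors))
    })
  }
  C <- ape::vcv(tree)
  Tdepth <- max(diag(C))
  Cm <- switch(model,
    BM = C,
    OU = {
      if (is.null(alpha) || alpha <= 0) abort("OU needs alpha > 0")
      exp(-2 * alpha * (Tdepth - C)) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
    },
    EB = {
      if (is.null(r) || r > 0) abort("EB needs r <= 0")
      if (abs(r) < 1e-12) C else (exp(r * C) - 1) / r
    })
  n <- nrow(C)
  mean <- rep_len(mean, n_traits)
  X <- with_seed_restore(seed, {
    Z <- matrix(rnorm(n * n_traits), n, n_traits)
    t(chol_psd(Cm)) %*% Z %*% chol_psd(rate)
  })
  X <- sweep(X, 2, mean, "+")
  colnames(X) <- paste0("V", seq_len(n_traits))
  out <- as_tibble(X)
  out <- mutate(out, species = rownames(C), .before = 1)
  out
}
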