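#' Configuration of the true mutational-effect landscape
#'
#' Defines, per structural/functional region of the protein, a mixture over
#' four effect components from which the true activity of each substitution
#' is drawn: `inactive` (activity 0), `intermediate` (Gaussian around 0.5),
#' `neutral` (activity 1, i.e. wild-type-like) and `enhancing` (Gaussian
#' above 1). Activities are on the wild-type = 1 scale and truncated to
#' `[0, a_max]`. Wild-type controls always have activity 1 and every
#' substitution at a critical residue has activity 0.
#'
#' Default regions mirror a 213-residue THAP-family factor: zinc finger
#' (2-81), disordered linker (82-138), a four-residue cofactor-binding motif
#' (134-137, overriding the linker), coiled-coil (139-191) and disordered
#' C-terminus (192-213). Structured regions are intolerant-heavy, disordered
#' regions neutral-heavy, the cofactor motif almost uniformly inactive.
#' Default critical residues are analogues of the four zinc-chelating
#' positions (5, 10, 54, 57).
#'
#' @param region_map Named list: class -> `c(start, end)` residue range
#'   (1-based inclusive). Overlaps are resolved in favour of the narrower
#'   region.
#' @param class_mixtures Named list: class -> numeric weights
#'   `c(inactive, intermediate, neutral, enhancing)` summing to 1.
#' @param component_params List with `intermediate = c(mean, sd)` and
#'   `enhancing = c(mean, sd)`.
#' @param critical_residues Integer positions whose every substitution has
#'   true activity 0.
#' @param a_max Upper truncation for activities (default 1.5).
#' @param seed RNG seed.
#' @return Object of class `landscape_config`.
#' @export
landscape_config <- function(
    region_map = list(zinc_finger = c(2L, 81L),
                      linker = c(82L, 138L),
                      hcfc1_motif = c(134L, 137L),
                      coiled_coil = c(139L, 191L),
                      cterm = c(192L, 213L)),
    class_mixtures = list(zinc_finger = c(0.55, 0.20, 0.20, 0.05),
                          linker = c(0.05, 0.10, 0.75, 0.10),
                          hcfc1_motif = c(0.90, 0.10, 0.00, 0.00),
                          coiled_coil = c(0.50, 0.20, 0.25, 0.05),
                          cterm = c(0.03, 0.07, 0.80, 0.10)),
    component_params = list(intermediate = c(mean = 0.5, sd = 0.15),
                            enhancing = c(mean = 1.3, sd = 0.10)),
    critical_residues = c(5L, 10L, 54L, 57L),
    a_max = 1.5,
    seed = NULL) {
  stopifnot(length(region_map) >= 1L, a_max > 0)
  if (!setequal(names(region_map), names(class_mixtures)))
    stop("`class_mixtures` must name exactly the classes of `region_map`",
         call. = FALSE)
  for (cl in names(class_mixtures)) {
    w <- class_mixtures[[cl]]
    if (length(w) != 4L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stop("mixture weights for class '", cl,
           "' must be 4 nonnegative values summing to 1", call. = FALSE)
  }
  structure(list(region_map = region_map, class_mixtures = class_mixtures,
                 component_params = component_params,
                 critical_residues = as.integer(critical_residues),
                 a_max = a_max, seed = seed),
            class = "landscape_config")
}

# Class of each position: the narrowest region containing it.
position_classes <- function(positions, region_map) {
  widths <- vapply(region_map, function(r) r[2] - r[1], numeric(1))
  ord <- names(region_map)[order(widths)]
  cls <- rep(NA_character_, length(positions))
  for (nm in rev(ord)) {             # widest first, narrower overwrite
    r <- region_map[[nm]]
    hit <- positions >= r[1] & positions <= r[2]
    cls[hit] <- nm
  }
  cls
}

#' Simulate the true activity of every library variant
#'
#' Assigns each variant a latent activity on the wild-type = 1 scale:
#' wild-type controls get exactly 1, substitutions at critical residues get
#' exactly 0, and all other substitutions draw from the region-class mixture
#' of the configuration. Deterministic under a fixed seed.
#'
#' @param design A [design_library()] result.
#' @param cfg A [landscape_config()].
#' @return Named numeric vector: variant id -> true activity.
#' @export
simulate_landscape <- function(design, cfg = landscape_config()) {
  stopifnot(inherits(design, "mutagenesis_design"),
            inherits(cfg, "landscape_config"))
  v <- design$variants
  cls <- position_classes(v$position, cfg$region_map)
  if (anyNA(cls)) {
    p <- v$position[which(is.na(cls))[1L]]
    stop("position ", p, " not covered by `region_map`", call. = FALSE)
  }
  with_seed_if(cfg$seed, {
    n <- nrow(v)
    a <- numeric(n)
    comp <- character(n)
    comps <- c("inactive", "intermediate", "neutral", "enhancing")
    for (cl in unique(cls)) {
      i <- which(cls == cl)
      comp[i] <- sample(comps, length(i), replace = TRUE,
                        prob = cfg$class_mixtures[[cl]])
    }
    a[comp == "neutral"] <- 1
    im <- cfg$component_params$intermediate
    en <- cfg$component_params$enhancing
    i <- which(comp == "intermediate")
    a[i] <- stats::rnorm(length(i), im[["mean"]], im[["sd"]])
    i <- which(comp == "enhancing")
    a[i] <- stats::rnorm(length(i), en[["mean"]], en[["sd"]])
    a <- pmin(pmax(a, 0), cfg$a_max)
    a[v$position %in% cfg$critical_residues] <- 0
    a[v$is_wt_control] <- 1
    stats::setNames(a, v$id)
  })
}
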