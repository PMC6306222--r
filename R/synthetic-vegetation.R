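#' Climate-niche rule for the synthetic vegetation generator
#'
#' A rectangular (box) climate niche: a vegetation class occupies every pixel
#' whose climate lies inside all of the rule's intervals. Intervals are
#' half-open `[low, high)` so adjacent rules partition cleanly along a shared
#' threshold. A rule with an empty `bounds` list matches everywhere and acts
#' as a fallback. When several rules match, the one with the smallest
#' `priority` value wins.
#'
#' @param class_id Class name (character) the rule assigns.
#' @param bounds Named list of `c(low, high)` intervals keyed by variable
#'   name; `low < high` required. May be empty (fallback rule).
#' @param priority Integer rank; unique across a rule set; smaller = higher
#'   priority.
#' @return An object of class `niche_rule`.
#' @export
niche_rule <- function(class_id, bounds = list(), priority = 1L) {
  stopifnot(is.character(class_id), length(class_id) == 1L)
  if (length(bounds)) {
    if (is.null(names(bounds)) || any(!nzchar(names(bounds)))) {
      stop("bounds must be named by variable", call. = FALSE)
    }
    for (v in names(bounds)) {
      b <- bounds[[v]]
      if (length(b) != 2L || !(b[1] < b[2])) {
        stop("bound for ", v, " must be c(low, high) with low < high",
             call. = FALSE)
      }
    }
  }
  structure(list(class_id = class_id, bounds = bounds,
                 priority = as.integer(priority)),
            class = "niche_rule")
}

check_rules <- function(rules) {
  if (!length(rules)) stop("at least one niche_rule required", call. = FALSE)
  prio <- vapply(rules, `[[`, integer(1), "priority")
  if (anyDuplicated(prio)) {
    stop("rule priorities must be unique", call. = FALSE)
  }
  invisible(rules[order(prio)])
}

rule_classes <- function(rules) {
  unique(vapply(rules, `[[`, character(1), "class_id"))
}

# bilinear upsampling of a coarse matrix to a (nrow*f) x (ncol*f) grid,
# interpolating between cell centres and clamping at the borders
bilinear_upsample <- function(m, f) {
  if (f == 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  up_axis <- function(n) {
    u <- (seq_len(n * f) - 0.5) / f + 0.5   # 1-based cell-centre coordinate
    i0 <- pmin(pmax(floor(u), 1L), max(n - 1L, 1L))
    t <- pmin(pmax(u - i0, 0), 1)
    list(i0 = as.integer(i0), t = t)
  }
  r <- up_axis(nr); c <- up_axis(nc)
  r1 <- pmin(r$i0 + 1L, nr); c1 <- pmin(c$i0 + 1L, nc)
  t <- matrix(r$t, nr * f, nc * f)
  s <- matrix(c$t, nr * f, nc * f, byrow = TRUE)
  (1 - t) * (1 - s) * m[r$i0, c$i0] + t * (1 - s) * m[r1, c$i0] +
    (1 - t) * s * m[r$i0, c1] + t * s * m[r1, c1]
}

# apply ordered rules to named list of layers (matrices); returns integer
# codes into `classes`; errors on uncovered climate
apply_niche_rules <- function(layers, rules, classes) {
  rules <- check_rules(rules)
  dims <- dim(layers[[1]])
  out <- matrix(NA_integer_, dims[1], dims[2])
  # lowest priority first so higher-priority rules overwrite
  for (rule in rev(rules)) {
    hit <- matrix(TRUE, dims[1], dims[2])
    for (v in names(rule$bounds)) {
      if (is.null(layers[[v]])) {
        stop("rule for class '", rule$class_id,
             "' references missing variable '", v, "'", call. = FALSE)
      }
      b <- rule$bounds[[v]]
      hit <- hit & layers[[v]] >= b[1] & layers[[v]] < b[2]
    }
    out[hit] <- match(rule$class_id, classes)
  }
  if (anyNA(out)) {
    idx <- which(is.na(out), arr.ind = TRUE)[1, ]
    clim <- vapply(layers, function(l) l[idx[1], idx[2]], numeric(1))
    stop("no niche rule matches pixel (row ", idx[1], ", col ", idx[2],
         ") with climate [",
         paste(names(clim), round(clim, 3), sep = "=", collapse = ", "),
         "] and no fallback rule is declared", call. = FALSE)
  }
  out
}

#' Generate a niche-driven vegetation map with known ground truth
#'
#' Labels a fine grid (`fine_factor` times the climate resolution) from the
#' niche rules evaluated on smoothly (bilinearly) interpolated climate, then
#' corrupts each pixel independently with probability `label_noise` by
#' flipping it to a uniformly chosen *other* class. The noise-free map is
#' returned alongside so downstream recovery can be tested against truth.
#'
#' @param surface Baseline [climate_surface()].
#' @param rules List of [niche_rule()] objects covering the realised climate
#'   (include a fallback rule if in doubt).
#' @param fine_factor Integer >= 1; fine grid is
#'   `(rows*fine_factor) x (cols*fine_factor)`.
#' @param label_noise Flip probability in `[0, 1)`. The expected fraction of
#'   pixels differing from truth is exactly `label_noise`.
#' @param seed Integer RNG seed.
#' @param classes Class vocabulary; defaults to the classes named by the
#'   rules, in rule order.
#' @return A list with elements `map` and `truth`, both
#'   [categorical_raster()] objects carrying `fine_factor`.
#' @export
generate_vegetation <- function(surface, rules, fine_factor = 1L,
                                label_noise = 0, seed,
                                classes = rule_classes(rules)) {
  fine_factor <- as.integer(fine_factor)
  if (fine_factor < 1L) stop("fine_factor must be >= 1", call. = FALSE)
  if (label_noise < 0 || label_noise >= 1) {
    stop("label_noise must be in [0, 1)", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  used <- unique(unlist(lapply(rules, function(r) names(r$bounds))))
  require_layers(surface, used)
  fine_layers <- lapply(surface$layers[union(used, names(surface$layers))],
                        bilinear_upsample, f = fine_factor)
  truth <- apply_niche_rules(fine_layers, rules, classes)
  labels <- truth
  k <- length(classes)
  if (label_noise > 0 && k > 1L) {
    set.seed(seed)
    n <- length(labels)
    flip <- stats::runif(n) < label_noise
    # uniform draw over the k-1 other classes
    offset <- sample.int(k - 1L, n, replace = TRUE)
    labels[flip] <- ((labels[flip] - 1L + offset[flip]) %% k) + 1L
  }
  if (!is.null(surface$mask)) {
    fine_mask <- surface$mask[rep(seq_len(surface$nrow), each = fine_factor),
                              rep(seq_len(surface$ncol), each = fine_factor)]
    labels[!fine_mask] <- NA_integer_
    truth[!fine_mask] <- NA_integer_
  }
  list(map = categorical_raster(labels, classes, fine_factor = fine_factor),
       truth = categorical_raster(truth, classes, fine_factor = fine_factor))
}
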