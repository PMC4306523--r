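#' @useDynLib bistableDCM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rgamma rnorm sd lm coef pt qt var setNames dgamma
#'   convolve runif quantile
#' @importFrom utils write.table read.delim
NULL

# Input labels used throughout: the four experimental conditions entering both
# the first-level GLM and the DCM input timeline.
DCM_INPUTS <- c("fixation", "stimulation", "rivalry_switch", "replay_switch")

#' Define the three-region hierarchy
#'
#' Builds the ordered region set for the structure-from-motion rivalry network:
#' right V5/MT at the bottom, right posterior SPL in the middle, right anterior
#' SPL at the top. The order defines hierarchy levels 0, 1, 2, and endogenous
#' connections are only allowed between adjacent levels (no direct V5--aSPL
#' edge).
#'
#' @param labels Character vector of exactly 3 region identifiers, ordered
#'   bottom to top.
#' @return An object of class `region_set` with fields `labels` and `level`.
#' @export
#' @examples
#' region_set()
region_set <- function(labels = c("rV5", "rpSPL", "raSPL")) {
  if (length(labels) != 3L || anyDuplicated(labels))
    stop("a region set has exactly 3 distinct regions (bottom to top)")
  structure(list(labels = as.character(labels),
                 level = setNames(0:2, labels)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region hierarchy (bottom -> top): ",
      paste(x$labels, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Modulable connections of the hierarchy
#'
#' The four inter-regional connections that may carry modulatory (B-matrix)
#' effects: the reciprocal pairs between adjacent hierarchy levels. Each is
#' classed bottom-up (lower to higher level) or top-down.
#'
#' @param regions A [region_set()].
#' @return A data.frame with columns `source`, `target`, `direction`
#'   (\"bottom_up\" or \"top_down\") and `label` (\"source->target\").
#' @export
modulable_connections <- function(regions = region_set()) {
  v5 <- regions$labels[1]; psp <- regions$labels[2]; asp <- regions$labels[3]
  con <- data.frame(
    source = c(asp, psp, psp, v5),
    target = c(psp, asp, v5, psp),
    stringsAsFactors = FALSE
  )
  lev <- regions$level
  con$direction <- ifelse(lev[con$source] < lev[con$target],
                          "bottom_up", "top_down")
  con$label <- paste0(con$source, "->", con$target)
  con
}

# endogenous adjacency shared by every model: self-loops plus the reciprocal
# adjacent-level pairs; the skip connection V5<->aSPL is absent by construction
endogenous_mask <- function(regions = region_set()) {
  n <- length(regions$labels)
  a <- diag(TRUE, n)
  dimnames(a) <- list(regions$labels, regions$labels)
  con <- modulable_connections(regions)
  for (i in seq_len(nrow(con))) a[con$target[i], con$source[i]] <- TRUE
  a
}

#' Enumerate the DCM hypothesis space
#'
#' Generates every candidate model: all subsets of the four modulable
#' connections (the same subset applies to the rivalry-switch and
#' replay-switch inputs) crossed with all subsets of the two free driving
#' inputs (aSPL and pSPL during switch events). V5 is driven during visual
#' stimulation and during both switch inputs in every model; no region is
#' driven during fixation. With the standard hierarchy this yields
#' 2^4 x 2^2 = 64 models.
#'
#' @param regions A [region_set()].
#' @param modulable Data.frame of candidate modulated connections, as
#'   returned by [modulable_connections()]. May be reduced (or emptied) for
#'   smaller enumeration variants.
#' @param free_input_regions Regions whose switch-event driving input is a
#'   free bit (default aSPL and pSPL).
#' @return A list of `dcm_model_spec` objects ordered by `model_id`. The id
#'   is a canonical integer: the modulation bits (in `modulable` row order)
#'   are the high bits, the free input bits the low bits, so enumeration
#'   order is stable across runs and platforms.
#' @export
#' @examples
#' length(enumerate_model_space())  # 64
enumerate_model_space <- function(regions = region_set(),
                                  modulable = modulable_connections(regions),
                                  free_input_regions = regions$labels[c(3, 2)]) {
  stopifnot(all(free_input_regions %in% regions$labels))
  nb <- nrow(modulable)
  nc <- length(free_input_regions)
  a_mask <- endogenous_mask(regions)
  models <- vector("list", 2^(nb + nc))
  k <- 0L
  for (bcode in seq_len(2^nb) - 1L) {
    bbits <- as.logical(bitwAnd(bcode, 2^(seq_len(nb) - 1L)) > 0)
    for (ccode in seq_len(2^nc) - 1L) {
      cbits <- as.logical(bitwAnd(ccode, 2^(seq_len(nc) - 1L)) > 0)
      k <- k + 1L
      models[[k]] <- new_dcm_model_spec(
        model_id = bcode * 2^nc + ccode,
        regions = regions, a_mask = a_mask,
        modulable = modulable, b_bits = bbits,
        free_input_regions = free_input_regions, c_bits = cbits)
    }
  }
  models[order(vapply(models, `[[`, 0L, "model_id"))]
}

new_dcm_model_spec <- function(model_id, regions, a_mask, modulable, b_bits,
                               free_input_regions, c_bits) {
  labs <- regions$labels
  n <- length(labs)
  b_mask <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  if (any(b_bits)) {
    sel <- modulable[b_bits, , drop = FALSE]
    for (i in seq_len(nrow(sel))) b_mask[sel$target[i], sel$source[i]] <- TRUE
  }
  c_mask <- matrix(FALSE, n, length(DCM_INPUTS),
                   dimnames = list(labs, DCM_INPUTS))
  c_mask[labs[1], c("stimulation", "rivalry_switch", "replay_switch")] <- TRUE
  driven <- free_input_regions[c_bits]
  c_mask[driven, c("rivalry_switch", "replay_switch")] <- TRUE
  structure(list(
    model_id = as.integer(model_id),
    regions = regions,
    a_mask = a_mask,
    b_mask = b_mask,                       # shared by both switch inputs
    b_connections = modulable$label[b_bits],
    b_directions = modulable$direction[b_bits],
    c_mask = c_mask,
    c_switch_regions = as.character(driven)
  ), class = "dcm_model_spec")
}

#' @export
print.dcm_model_spec <- function(x, ...) {
  cat(sprintf("DCM model %d: modulation {%s}; switch input to {%s}\n",
              x$model_id,
              paste(x$b_connections, collapse = ", "),
              paste(c(x$regions$labels[1], x$c_switch_regions),
                    collapse = ", ")))
  invisible(x)
}

FAMILY_NAMES <- c("no_modulation", "bottom_up", "top_down", "bidirectional")

#' Classify a model into its modulatory family
#'
#' A model belongs to `no_modulation` if it modulates no connection, to
#' `bottom_up` (`top_down`) if it modulates at least one bottom-up (top-down)
#' connection and none of the other class, and to `bidirectional` if it
#' modulates at least one of each.
#'
#' @param model A `dcm_model_spec`.
#' @return One of `"no_modulation"`, `"bottom_up"`, `"top_down"`,
#'   `"bidirectional"`.
#' @export
classify_family <- function(model) {
  dirs <- model$b_directions
  if (!all(dirs %in% c("bottom_up", "top_down")))
    stop("unknown connection direction in modulation mask")
  has_bu <- any(dirs == "bottom_up")
  has_td <- any(dirs == "top_down")
  if (!has_bu && !has_td) "no_modulation"
  else if (has_bu && !has_td) "bottom_up"
  else if (!has_bu && has_td) "top_down"
  else "bidirectional"
}

#' Partition the model space into the four families
#'
#' @param models The full enumeration from [enumerate_model_space()].
#' @return A list of four `model_family` objects (name, member_ids), in the
#'   order no_modulation, bottom_up, top_down, bidirectional. For the
#'   standard 64-model space the family sizes are 4, 12, 12 and 36.
#' @export
partition_families <- function(models) {
  ids <- vapply(models, `[[`, 0L, "model_id")
  if (anyDuplicated(ids)) stop("duplicate model_id in model list")
  fam <- vapply(models, classify_family, "")
  lapply(FAMILY_NAMES, function(nm) {
    structure(list(name = nm, member_ids = ids[fam == nm]),
              class = "model_family")
  })
}

#' @export
print.model_family <- function(x, ...) {
  cat(sprintf("Family '%s': %d models\n", x$name, length(x$member_ids)))
  invisible(x)
}

#' Tabular view of a model space
#'
#' One row per model: id, family, one logical column per modulable
#' connection, one per free switch-driven region.
#'
#' @param models List of `dcm_model_spec`.
#' @return A data.frame keyed by `model_id`.
#' @export
model_space_table <- function(models) {
  modulable <- modulable_connections(models[[1]]$regions)
  free_regions <- models[[1]]$regions$labels[c(3, 2)]
  tab <- data.frame(
    model_id = vapply(models, `[[`, 0L, "model_id"),
    family = vapply(models, classify_family, "")
  )
  for (lab in modulable$label)
    tab[[paste0("b.", lab)]] <-
      vapply(models, function(m) lab %in% m$b_connections, NA)
  for (r in free_regions)
    tab[[paste0("c.", r)]] <-
      vapply(models, function(m) r %in% m$c_switch_regions, NA)
  tab
}

#' Write / read a model space as tab-separated text
#'
#' @param models List of `dcm_model_spec`.
#' @param path Output file.
#' @return `write_model_space` returns `path` invisibly; `read_model_space`
#'   rebuilds the list of `dcm_model_spec` from the table.
#' @export
write_model_space <- function(models, path) {
  write.table(model_space_table(models), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_model_space
#' @param regions Region set used to rebuild the specs.
#' @export
read_model_space <- function(path, regions = region_set()) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  modulable <- modulable_connections(regions)
  free_regions <- regions$labels[c(3, 2)]
  a_mask <- endogenous_mask(regions)
  models <- lapply(seq_len(nrow(tab)), function(i) {
    bbits <- as.logical(unlist(tab[i, paste0("b.", modulable$label)]))
    cbits <- as.logical(unlist(tab[i, paste0("c.", free_regions)]))
    new_dcm_model_spec(tab$model_id[i], regions, a_mask,
                       modulable, bbits, free_regions, cbits)
  })
  models[order(vapply(models, `[[`, 0L, "model_id"))]
}
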