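#' Phenotype group
#'
#' A named compartment of the modelled cell population. Each group carries a
#' growth dose-response to the inhibitory factor, a dimensionless
#' gene-expression weight `w` (its relative contribution to factor
#' secretion), and a flag marking membership in the CD34+ readout
#' compartment.
#'
#' @param id Short label, unique within a model.
#' @param growth A [growth_correlation()].
#' @param w Expression weight, `>= 0`.
#' @param is_cd34 Logical; does this group count toward the CD34+ readout?
#' @param members Character vector of member phenotype definitions
#'   (informational only).
#' @return An object of class `phenotype_group`.
#' @export
phenotype_group <- function(id, growth, w = 1, is_cd34 = FALSE,
                            members = character()) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id),
            inherits(growth, "growth_correlation"))
  if (!is.finite(w) || w < 0) stop("expression weight must be >= 0", call. = FALSE)
  structure(list(id = id, growth = growth, w = as.numeric(w),
                 is_cd34 = isTRUE(is_cd34),
                 members = as.character(members)),
            class = "phenotype_group")
}

#' Culture model
#'
#' Bundles the phenotype groups, the secretion correlation and the culture
#' seeding parameters into the full empirical model: cells grow at
#' concentration-dependent rates, secrete the factor in proportion to the
#' expression-weighted cell number, and the concentration closure is
#' `C = M / V` (factor amount over culture volume).
#'
#' @param groups List of [phenotype_group()]s with unique ids; at least one
#'   must have `is_cd34 = TRUE`.
#' @param secretion A [secretion_correlation()].
#' @param V0 Initial culture volume, mL, `> 0`.
#' @param seed_density Seeding density, cells/mL, `> 0`.
#' @return An object of class `culture_model`.
#' @export
culture_model <- function(groups, secretion, V0 = 1, seed_density = 1e5) {
  stopifnot(is.list(groups), length(groups) >= 1,
            all(vapply(groups, inherits, TRUE, "phenotype_group")),
            inherits(secretion, "secretion_correlation"))
  ids <- vapply(groups, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("group ids must be unique", call. = FALSE)
  members <- unlist(lapply(groups, `[[`, "members"))
  if (anyDuplicated(members))
    stop("a phenotype may not belong to two groups", call. = FALSE)
  if (!any(vapply(groups, `[[`, TRUE, "is_cd34")))
    stop("at least one group must be flagged is_cd34", call. = FALSE)
  if (!is.finite(V0) || V0 <= 0) stop("V0 must be > 0", call. = FALSE)
  if (!is.finite(seed_density) || seed_density <= 0)
    stop("seed_density must be > 0", call. = FALSE)
  names(groups) <- ids
  structure(list(groups = groups, secretion = secretion,
                 V0 = as.numeric(V0), seed_density = as.numeric(seed_density)),
            class = "culture_model")
}

#' @export
print.culture_model <- function(x, ...) {
  cat(sprintf("culture_model: %d phenotype groups, V0 = %g mL, seed %g cells/mL\n",
              length(x$groups), x$V0, x$seed_density))
  for (g in x$groups)
    cat(sprintf("  %-12s w = %-5.3g %s %s\n", g$id, g$w,
                if (g$is_cd34) "[CD34+]" else "       ", g$growth$kind))
  print(x$secretion)
  invisible(x)
}

group_ids <- function(model) vapply(model$groups, `[[`, "", "id")
group_weights <- function(model) vapply(model$groups, `[[`, 0, "w")
cd34_flags <- function(model) vapply(model$groups, `[[`, TRUE, "is_cd34")

#' Culture state
#'
#' Snapshot of a fed-batch culture: per-group cell numbers `N`, total factor
#' amount `M` (pg), culture volume `V` (mL), cumulative added volume
#' `V_added`, cumulative media consumption `media_used` (additions plus
#' exchange replacements) and time `t` (days). Concentration is the derived
#' quantity `M / V`.
#'
#' @param N Named numeric vector of cell numbers per group, `>= 0`.
#' @param M Factor amount, pg, `>= 0`.
#' @param V Culture volume, mL, `> 0`.
#' @param t Time, days.
#' @param V_added Cumulative added volume, mL.
#' @param media_used Cumulative fresh-media consumption, mL (defaults to
#'   `V_added`).
#' @return An object of class `culture_state`.
#' @export
culture_state <- function(N, M = 0, V = 1, t = 0, V_added = 0,
                          media_used = V_added) {
  if (is.null(names(N)) || any(!nzchar(names(N))))
    stop("N must be a named vector (group ids)", call. = FALSE)
  if (any(!is.finite(N)) || any(N < 0)) stop("cell numbers must be >= 0", call. = FALSE)
  if (!is.finite(M) || M < 0) stop("factor amount must be >= 0", call. = FALSE)
  if (!is.finite(V) || V <= 0) stop("volume must be > 0", call. = FALSE)
  structure(list(t = as.numeric(t), N = N, M = as.numeric(M),
                 V = as.numeric(V), V_added = as.numeric(V_added),
                 media_used = as.numeric(media_used)),
            class = "culture_state")
}

#' @export
print.culture_state <- function(x, ...) {
  cat(sprintf("culture_state @ day %.3g: %.4g cells, M = %.4g pg, V = %.4g mL (C = %.4g pg/mL)\n",
              x$t, sum(x$N), x$M, x$V, concentration(x)))
  invisible(x)
}

#' Factor concentration of a culture state
#'
#' @param state A [culture_state()].
#' @return Concentration `M / V`, pg/mL.
#' @export
concentration <- function(state) state$M / state$V

#' Initial culture state for a model
#'
#' Seeds `seed_density * V0` total cells, split across groups either by the
#' supplied fractions or counts.
#'
#' @param model A [culture_model()].
#' @param N0 Optional named vector of initial counts per group; defaults to
#'   an even split of the seed total.
#' @return A [culture_state()] at `t = 0`, `M = 0`, `V = V0`.
#' @export
initial_state <- function(model, N0 = NULL) {
  ids <- group_ids(model)
  if (is.null(N0)) {
    total <- model$seed_density * model$V0
    N0 <- stats::setNames(rep(total / length(ids), length(ids)), ids)
  }
  if (!setequal(names(N0), ids))
    stop("N0 names must match the model's group ids", call. = FALSE)
  culture_state(N = N0[ids], M = 0, V = model$V0, t = 0)
}

#' Expression-weighted ("adjusted") cell number
#'
#' The weighted sum over groups, `sum(w_g * N_g)` — the model's predictor of
#' the net factor secretion rate.
#'
#' @param state A [culture_state()].
#' @param model A [culture_model()].
#' @return Adjusted cell number (dimensionless-weighted count).
#' @export
adjusted_cell_number <- function(state, model) {
  ids <- group_ids(model)
  sum(group_weights(model) * as.numeric(state$N[ids]))
}

#' Time derivative of the culture state
#'
#' The model right-hand side: each group grows at its correlation's rate
#' evaluated at the current concentration `C = M/V`; the factor amount grows
#' at the net secretion rate of the adjusted cell number; volume changes only
#' by inflow. Dilution acts purely through `V` — fed-batch addition removes
#' no factor mass.
#'
#' @param state A [culture_state()].
#' @param model A [culture_model()].
#' @param inflow Media inflow, mL/day, `>= 0`.
#' @return List with components `dN` (named, cells/day), `dM` (pg/day),
#'   `dV` (mL/day).
#' @export
state_derivative <- function(state, model, inflow = 0) {
  if (!is.finite(state$V) || state$V <= 0)
    stop("invalid state: volume must be > 0", call. = FALSE)
  if (inflow < 0) stop("inflow must be >= 0", call. = FALSE)
  C <- state$M / state$V
  rates <- vapply(model$groups, function(g) evaluate_growth_rate(g$growth, C), 0)
  dN <- rates * as.numeric(state$N[group_ids(model)])
  names(dN) <- group_ids(model)
  adj <- adjusted_cell_number(state, model)
  list(dN = dN, dM = net_secretion_rate(adj, model$secretion), dV = inflow)
}
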