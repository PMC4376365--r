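#' Stoichiometric metabolic model
#'
#' A constraint-based model: stoichiometric matrix, flux bounds, a biomass
#' objective reaction, named exchange reactions for the substrates tracked
#' in the spatial simulation, and optional per-reaction molecular-crowding
#' coefficients. Exchange reactions follow the usual convention of
#' export-positive flux (uptake is a negative exchange flux); the spatial
#' layer's uptake-positive constraint vectors are converted at the LP
#' boundary.
#'
#' @param S stoichiometric matrix, metabolites x reactions, with dimnames
#' @param lb,ub named reaction bounds, mmol gDwt^-1 hr^-1
#' @param objective reaction id of the biomass objective
#' @param exchanges named character vector mapping each tracked substrate
#'   to its exchange reaction id
#' @param crowding optional named numeric of crowding coefficients a_r
#'   (gDwt hr mmol^-1); the crowding constraint is sum_r a_r |v_r| <= 1
#' @return an object of class `metabolic_model`
#' @export
metabolic_model <- function(S, lb, ub, objective, exchanges, crowding = NULL) {
  S <- as.matrix(S)
  stopifnot(!is.null(rownames(S)), !is.null(colnames(S)))
  rxns <- colnames(S)
  stopifnot(setequal(names(lb), rxns), setequal(names(ub), rxns),
            objective %in% rxns, all(exchanges %in% rxns),
            !is.null(names(exchanges)), !anyDuplicated(exchanges))
  if (!is.null(crowding)) {
    stopifnot(all(names(crowding) %in% rxns), all(crowding >= 0))
    cr <- stats::setNames(numeric(length(rxns)), rxns)
    cr[names(crowding)] <- crowding
    crowding <- cr
  }
  structure(list(S = S, lb = lb[rxns], ub = ub[rxns], objective = objective,
                 exchanges = exchanges, crowding = crowding),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$S), "metabolites x", ncol(x$S), "reactions\n")
  cat(" objective:", x$objective, "\n")
  cat(" tracked exchanges:",
      paste(names(x$exchanges), x$exchanges, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$crowding)) cat(" crowding coefficients present\n")
  invisible(x)
}

#' A regulatory cell state: constraint overrides on a shared model
#'
#' Overrides may only tighten the base model's bounds; the canonical uses
#' are the glucose-consuming state (acetate uptake forbidden, i.e. a lower
#' bound of 0 on the acetate exchange) and the acetate-consuming state
#' (glucose uptake forbidden).
#'
#' @param id state id
#' @param overrides named list of length-2 numeric `c(lb, ub)` per reaction
#' @return an object of class `cell_state`
#' @export
cell_state <- function(id, overrides = list()) {
  stopifnot(is.character(id), length(id) == 1L)
  stopifnot(all(vapply(overrides, length, 0L) == 2L))
  structure(list(id = id, overrides = overrides), class = "cell_state")
}

# Effective bounds for a state on a model (overrides intersect the base
# bounds, so they can only tighten).
state_bounds <- function(model, state) {
  lb <- model$lb; ub <- model$ub
  if (!is.null(state)) for (rxn in names(state$overrides)) {
    ov <- state$overrides[[rxn]]
    lb[rxn] <- max(lb[rxn], ov[1L])
    ub[rxn] <- min(ub[rxn], ov[2L])
  }
  list(lb = lb, ub = ub)
}

flux_solution <- function(g, v_exchange, feasible, fluxes = NULL) {
  structure(list(g = g, v_exchange = v_exchange, feasible = feasible,
                 fluxes = fluxes), class = "flux_solution")
}

# Split-variable LP core shared by both FBA stages: v = p - q with
# p, q >= 0, so the crowding constraint and the parsimonious objective
# (both functions of |v|) stay linear.
fba_lp <- function(S, lb, ub, obj_rxn, crowding_vec = NULL,
                   fix_obj = NULL, minimize_total = FALSE) {
  n <- ncol(S)
  p_lb <- pmax(0, lb); p_ub <- pmax(0, ub)
  q_lb <- pmax(0, -ub); q_ub <- pmax(0, -lb)
  Aeq <- cbind(S, -S)
  beq <- numeric(nrow(S))
  j <- match(obj_rxn, colnames(S))
  if (!is.null(fix_obj)) {
    row <- numeric(2L * n); row[j] <- 1; row[n + j] <- -1
    Aeq <- rbind(Aeq, row)
    beq <- c(beq, fix_obj)
  }
  ineq_A <- NULL; ineq_b <- NULL
  if (!is.null(crowding_vec)) {
    ineq_A <- matrix(c(crowding_vec, crowding_vec), nrow = 1L)
    ineq_b <- 1
  }
  if (minimize_total) {
    obj <- rep(1, 2L * n); maximize <- FALSE
  } else {
    obj <- numeric(2L * n); obj[j] <- 1; obj[n + j] <- -1; maximize <- TRUE
  }
  res <- lp_bounded(obj, Aeq, beq, lb = c(p_lb, q_lb), ub = c(p_ub, q_ub),
                    ineq_A = ineq_A, ineq_b = ineq_b, maximize = maximize)
  if (res$status != 1L) return(NULL)
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- colnames(S)
  list(v = v, value = res$value)
}

#' Solve the per-site flux balance problem
#'
#' Maximizes the biomass objective subject to steady state, the model and
#' state bounds, per-substrate availability constraints, and (optionally)
#' the molecular-crowding budget `sum_r a_r |v_r| <= 1`. Alternate optima
#' are resolved by a parsimonious second stage that minimizes total
#' absolute flux at the fixed optimal growth rate, making the reported
#' exchange fluxes unique and the lookup tables reproducible.
#'
#' @param model a [metabolic_model()]
#' @param state an optional [cell_state()] whose overrides tighten bounds
#' @param constraints named non-negative numeric: maximum specific uptake
#'   (mmol gDwt^-1 hr^-1) per tracked substrate; uptake-positive
#' @param crowding apply the crowding constraint (requires coefficients on
#'   the model)?
#' @return a `flux_solution`: growth rate `g` (hr^-1), named uptake-positive
#'   exchange fluxes `v_exchange` for the tracked substrates, a `feasible`
#'   flag, and the full flux vector. Infeasible problems return
#'   `g = 0` with zero exchanges and `feasible = FALSE`.
#' @export
solve_fba <- function(model, state = NULL, constraints = NULL,
                      crowding = FALSE) {
  sb <- state_bounds(model, state)
  lb <- sb$lb; ub <- sb$ub
  if (!is.null(constraints)) {
    if (any(constraints < 0)) stop("availability constraints must be non-negative")
    for (s in names(constraints)) {
      rxn <- model$exchanges[[s]]
      if (is.null(rxn)) stop("no exchange reaction for substrate ", s)
      lb[rxn] <- max(lb[rxn], -constraints[[s]])
    }
  }
  cr <- if (crowding) {
    if (is.null(model$crowding)) stop("model carries no crowding coefficients")
    model$crowding
  }
  zero <- stats::setNames(numeric(length(model$exchanges)), names(model$exchanges))
  s1 <- fba_lp(model$S, lb, ub, model$objective, crowding_vec = cr)
  if (is.null(s1)) return(flux_solution(0, zero, FALSE))
  g <- max(0, s1$value)
  s2 <- fba_lp(model$S, lb, ub, model$objective, crowding_vec = cr,
               fix_obj = s1$value, minimize_total = TRUE)
  v <- if (is.null(s2)) s1$v else s2$v
  v_ex <- -v[model$exchanges]          # convert to uptake-positive
  names(v_ex) <- names(model$exchanges)
  flux_solution(g, v_ex, TRUE, fluxes = v)
}

#' Rank fermentation products secreted at maximal growth
#'
#' Solves the model with glucose at its kinetic cap, oxygen fully available
#' (aerobic) or absent (anaerobic), and no acetate uptake, then reports all
#' non-zero secretion fluxes in descending order. Used to decide which
#' byproducts are worth tracking in the spatial simulation.
#'
#' @param model a [metabolic_model()]
#' @param aerobic logical
#' @param o2_cap oxygen availability in the aerobic case,
#'   mmol gDwt^-1 hr^-1
#' @param tol secretion fluxes below `tol` are dropped
#' @return data.frame with columns `reaction` and `flux` (secretion
#'   positive), sorted by decreasing flux
#' @export
fermentation_screen <- function(model, aerobic = FALSE, o2_cap = 31.8,
                                tol = 1e-9) {
  caps <- stats::setNames(numeric(length(model$exchanges)), names(model$exchanges))
  if ("glc" %in% names(caps)) caps["glc"] <- -model$lb[model$exchanges[["glc"]]]
  if ("o2" %in% names(caps)) caps["o2"] <- if (aerobic) o2_cap else 0
  sol <- solve_fba(model, constraints = caps)
  if (!sol$feasible || is.null(sol$fluxes))
    return(data.frame(reaction = character(), flux = numeric()))
  # exchange reactions: columns touching exactly one metabolite (the
  # biomass pseudo-reaction is not a transport process)
  is_ex <- colSums(model$S != 0) == 1L
  ex_ids <- setdiff(colnames(model$S)[is_ex], model$objective)
  secreted <- sol$fluxes[ex_ids]
  secreted <- secreted[secreted > tol]
  out <- data.frame(reaction = names(secreted), flux = as.numeric(secreted))
  out[order(-out$flux), , drop = FALSE]
}
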