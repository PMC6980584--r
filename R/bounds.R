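#' Flux bound policy
#'
#' Standard bound conventions for a photoautotrophic model, in mmol/gDCW/h:
#' intracellular reversible reactions get (-1000, 1000), intracellular
#' irreversible reactions (0, 1000), exchange reactions (0, 1000) except a
#' set of freely exchanged species (water, protons, inorganic ions; lower
#' bound -1000) and a set of limited nutrient uptakes (bicarbonate, nitrate,
#' photon; lower bound -10 unless overridden per reaction).
#'
#' Sets are keyed by exchange reaction id; ids absent from a model are
#' ignored when the policy is applied, so one policy serves many models.
#'
#' @param free_exchange_ids character vector of exchange reaction ids whose
#'   lower bound is opened to `-big`.
#' @param limited_exchange named numeric vector: exchange reaction id ->
#'   (negative) lower bound.
#' @param big magnitude used for unconstrained bounds.
#' @return an object of class `bound_policy`.
#' @export
bound_policy <- function(free_exchange_ids = c("EX_h", "EX_h2o", "EX_k",
                                               "EX_so4", "EX_pi"),
                         limited_exchange = c(EX_hco3 = -10, EX_no3 = -10,
                                              EX_photon = -10),
                         big = 1000) {
  both <- intersect(free_exchange_ids, names(limited_exchange))
  if (length(both)) {
    stop("exchange id in both free and limited sets: ", both[1])
  }
  if (any(limited_exchange > 0)) stop("limited uptake bounds must be <= 0")
  structure(list(free_exchange_ids = free_exchange_ids,
                 limited_exchange = limited_exchange,
                 big = big),
            class = "bound_policy")
}

#' Apply a bound policy to a model
#'
#' Reversibility of intracellular reactions is read from the sign of the
#' current lower bound, so the operation is idempotent.
#'
#' @param model a `metabolic_model`.
#' @param policy a [bound_policy()].
#' @return the model with rewritten bounds.
#' @export
apply_bound_policy <- function(model, policy = bound_policy()) {
  stopifnot(inherits(policy, "bound_policy"))
  big <- policy$big
  ex <- is_exchange_reaction(model)
  rev <- model$reactions$lower_bound < 0
  model$reactions$lower_bound <- ifelse(ex, 0, ifelse(rev, -big, 0))
  model$reactions$upper_bound <- big
  free <- model$reactions$id %in% policy$free_exchange_ids & ex
  model$reactions$lower_bound[free] <- -big
  lim <- intersect(names(policy$limited_exchange), model$reactions$id[ex])
  if (length(lim)) {
    k <- match(lim, model$reactions$id)
    model$reactions$lower_bound[k] <- policy$limited_exchange[lim]
  }
  validate_model(model)
}
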