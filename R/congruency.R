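#' Additive expectation for the bimodal response
#'
#' The rule table mapping the pair of unimodal response labels (IV, VCN)
#' to the expected bimodal label under additivity. Of the nine label
#' pairs, seven yield a clear expectation; the two opposite-sign pairs
#' (excited/inhibited and inhibited/excited) cannot predict the additive
#' outcome — it would depend on the relative strengths of excitation and
#' inhibition — and return `"no_rule"`.
#'
#' @param iv,vcn Unimodal labels: `"excited"`, `"inhibited"` or
#'   `"nonresponsive"`.
#' @return The expected bimodal label, or `"no_rule"`.
#' @examples
#' expected_bimodal("excited", "excited")         # "excited"
#' expected_bimodal("excited", "nonresponsive")   # "excited"
#' expected_bimodal("excited", "inhibited")       # "no_rule"
#' @export
expected_bimodal <- function(iv, vcn) {
  labs <- c("excited", "inhibited", "nonresponsive")
  if (!(is.character(iv) && length(iv) == 1L && iv %in% labs))
    abort_bad_arg("iv", "must be one of excited/inhibited/nonresponsive")
  if (!(is.character(vcn) && length(vcn) == 1L && vcn %in% labs))
    abort_bad_arg("vcn", "must be one of excited/inhibited/nonresponsive")
  if (iv == vcn) return(iv)
  if (iv == "nonresponsive") return(vcn)
  if (vcn == "nonresponsive") return(iv)
  "no_rule"  # excited/inhibited in opposite directions
}

#' The full 3 x 3 expectation rule table
#'
#' @return Data frame enumerating all nine (IV, VCN) label pairs and the
#'   expected bimodal outcome (`"no_rule"` for the two inconclusive
#'   pairs).
#' @export
expectation_rule_table <- function() {
  labs <- c("excited", "inhibited", "nonresponsive")
  grid <- expand.grid(iv = labs, vcn = labs, stringsAsFactors = FALSE)
  grid$expected <- mapply(expected_bimodal, grid$iv, grid$vcn)
  grid
}

#' Score bimodal congruency against additive expectations
#'
#' Boolean comparison of each neuron's observed bimodal label with the
#' additive expectation from its unimodal labels: `congruent` when they
#' match, `incongruent` when an expectation exists and differs, `no_rule`
#' when no expectation can be formed. Verdicts are computed on labels, not
#' firing-frequency changes — the conservative choice, since
#' frequency-based expectations are sensitive to the nonlinearity of F/I
#' curves.
#'
#' @param map A response map (see [build_response_map()]) with `IV`,
#'   `VCN` and `bimodal` labels for every neuron.
#' @return List of class `congruency_report`: `neurons` (data frame with
#'   `neuron_id`, `expected`, `observed`, `verdict`) and `proportions`
#'   (percentages of congruent / incongruent / no_rule, summing to 100).
#' @export
score_congruency <- function(map) {
  wide <- label_matrix(map, c("IV", "VCN", "bimodal"))
  expected <- mapply(expected_bimodal, wide[, "IV"], wide[, "VCN"])
  observed <- wide[, "bimodal"]
  verdict <- ifelse(expected == "no_rule", "no_rule",
                    ifelse(expected == observed, "congruent", "incongruent"))
  props <- 100 * vapply(c("congruent", "incongruent", "no_rule"),
                        function(v) mean(verdict == v), numeric(1))
  structure(list(
    neurons = data.frame(neuron_id = rownames(wide),
                         expected = unname(expected),
                         observed = unname(observed),
                         verdict = unname(verdict),
                         stringsAsFactors = FALSE),
    proportions = props),
    class = "congruency_report")
}

#' @export
print.congruency_report <- function(x, ...) {
  p <- x$proportions
  cat(sprintf(
    "<congruency_report> %d neurons: %.1f%% congruent, %.1f%% incongruent, %.1f%% no rule\n",
    nrow(x$neurons), p[["congruent"]], p[["incongruent"]], p[["no_rule"]]))
  invisible(x)
}
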