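#' The packaged "Country X" worked example
#'
#' A complete, self-contained example prioritization: five criteria
#' (bioterrorism potential, severity of illness in humans, economic burden,
#' amenability to collaborate, epidemic potential) with the running-example
#' questions and scales; ten constructed participant judgment sets whose
#' group aggregate ranks severity first, then bioterrorism, economic burden,
#' collaboration, epidemic potential (so sequential weights are 5, 4, 3, 2,
#' 1 in that order); and a 20-disease answer table — including a grouped
#' "Bacterial Food-Borne Zoonoses" entry — in which rabies answers yes / no /
#' no / both / yes and therefore totals 5 + 0 + 0 + 2 + 1 = 8.
#'
#' The judgment sets are constructed, not elicited: each participant's
#' matrix is the consistent matrix of the latent vector (5, 4, 3, 2, 1)
#' raised element-wise to a participant-specific exponent in \[0.8, 1.25\],
#' so individual intensity varies but every participant is perfectly
#' consistent and the aggregate ordering is the example's.
#'
#' @return List with elements `config` ([prioritization_config()]),
#'   `judgments` (list of [participant_judgment()]), `answers`
#'   ([answer_table()]).
#' @export
#' @examples
#' fx <- fixture_country_x()
#' length(fx$config$criteria)  # 5
fixture_country_x <- function() {
  root <- system.file("extdata", "country_x", package = "zooprior")
  if (!nzchar(root)) stop("packaged Country X fixture not found")
  config <- load_config(file.path(root, "config.yaml"))
  judgments <- load_judgments(file.path(root, "judgments"), config)
  answers <- load_answers(file.path(root, "answers.csv"), config)
  list(config = config, judgments = judgments, answers = answers)
}

#' The packaged example criteria library configuration
#'
#' An eight-criterion example configuration assembled from the tool's
#' criteria handout (transmission potential, epidemic potential, pandemic
#' potential, bioterrorism potential, amenability to collaborate, economic
#' burden, severity of illness, ability to prevent/control), each paired
#' with one of its candidate categorical questions, over the same 20-disease
#' example list. Useful as a starting point for configuring a real exercise.
#'
#' @param strict Passed to [load_config()].
#' @return A [prioritization_config()] with 8 criteria.
#' @export
fixture_example_criteria <- function(strict = FALSE) {
  path <- system.file("extdata", "example_criteria.yaml", package = "zooprior")
  if (!nzchar(path)) stop("packaged example criteria configuration not found")
  load_config(path, strict = strict)
}
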