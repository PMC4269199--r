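#' Load a packaged data fixture
#'
#' The package ships machine-readable transcriptions of the published
#' site tables of a South African thermal-spring / deep-subsurface survey,
#' plus small demonstration inputs:
#' \describe{
#'   \item{table2_springs}{physical/chemical properties of the 6 thermal
#'     springs (DMS coordinates parsed to decimal degrees, temperature and
#'     pH ranges to midpoints with *_min/*_max columns).}
#'   \item{table3_subsurface}{the same for the 7 fracture-water samples,
#'     including sampling depth (mbs).}
#'   \item{table4_diversity}{per-site read counts, observed genera,
#'     Pielou's evenness and Chao1 +/- SE for all 13 datasets.}
#'   \item{shared_genera}{printed pairwise shared-genus counts used for
#'     Sorensen worked examples.}
#'   \item{contaminant_genera_demo}{a small demonstration list of genera
#'     flagged as potential mining contaminants (not the full published
#'     database).}
#'   \item{springs_genus_counts_synthetic}{a synthetic genus-level count
#'     table for 6 spring-like sites whose per-site read totals match the
#'     published spring totals; generated, not observed, data.}
#' }
#'
#' @param name one of the fixture names above.
#' @return A data.frame, \code{community_table} or character vector,
#'   depending on the fixture.
#' @export
load_fixture <- function(name = c("table2_springs", "table3_subsurface",
                                  "table4_diversity", "shared_genera",
                                  "contaminant_genera_demo",
                                  "springs_genus_counts_synthetic")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, switch(name,
    contaminant_genera_demo = ".txt", ".tsv")), package = "deepspring")
  if (path == "") stop("fixture not installed: ", name)
  switch(name,
    table2_springs = read_site_metadata(path),
    table3_subsurface = read_site_metadata(path),
    table4_diversity = utils::read.delim(path, stringsAsFactors = FALSE),
    shared_genera = utils::read.delim(path, stringsAsFactors = FALSE),
    contaminant_genera_demo = {
      x <- readLines(path)
      x <- trimws(x[!grepl("^#", x)])
      x[nzchar(x)]
    },
    springs_genus_counts_synthetic = read_community_table(path))
}
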