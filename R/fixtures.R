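# Packaged chlorogenic-acid (CGA) ultrasound-assisted extraction study data:
# factor coding, the 27-run CCRD with duplicate-mean yields, and the 4-run
# external validation set. Files are plain TSV under inst/extdata and are
# checksummed on load so silent corruption cannot propagate into analyses.

.fixture_files <- c(
  factors    = "cga_factors.tsv",
  runs       = "cga_ccrd.tsv",
  validation = "cga_validation.tsv"
)

.fixture_md5 <- c(
  cga_factors.tsv    = "a3c585b262afe82f2715866727cbe75a",
  cga_ccrd.tsv       = "010dfcffda1f43337c70d2e1995cc725",
  cga_validation.tsv = "3205cb4c4da68c72fd57c86e1701e377"
)

fixture_path <- function(file, dir = NULL) {
  path <- if (is.null(dir)) {
    system.file("extdata", file, package = "extractopt", mustWork = TRUE)
  } else {
    file.path(dir, file)
  }
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[[file]]))) {
    stop("corrupted fixture: checksum mismatch for ", file, call. = FALSE)
  }
  path
}

#' Load a packaged data set from the CGA extraction study
#'
#' Three fixtures ship with the package: `"factors"` (the four process
#' factors with their centers and per-coded-unit steps), `"runs"` (the
#' 27-run five-level CCRD with measured chlorogenic-acid yields in mg per g
#' dried flower, duplicate-determination standard deviations, and the
#' originally reported surrogate predictions), and `"validation"` (four
#' external runs not used for fitting). Files are verified against stored
#' checksums at load time.
#'
#' @param name One of `"factors"`, `"runs"`, `"validation"`.
#' @return A tibble. For `"runs"` and `"validation"` the factor table is
#'   attached as attribute `"factors"` so fitting functions can recover the
#'   coding without extra arguments.
#' @export
#' @examples
#' runs <- load_fixture("runs")
#' range(runs$yield)
load_fixture <- function(name = c("factors", "runs", "validation")) {
  name <- match.arg(name)
  path <- fixture_path(.fixture_files[[name]])
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (name == "factors") return(tab)
  attr(tab, "factors") <- load_fixture("factors")
  tab
}

#' @rdname load_fixture
#' @export
cga_factors <- function() load_fixture("factors")

#' @rdname load_fixture
#' @export
cga_runs <- function() load_fixture("runs")

#' @rdname load_fixture
#' @export
cga_validation <- function() load_fixture("validation")
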