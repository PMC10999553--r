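# The genome-scale model of S. fredii CCBAU45436 and its companion
# proteome tables are distributed through the authors' repository and are
# not redistributed with this package. When a copy is placed under
# inst/extdata/ the reproduction tests below run against it; without it
# they fail with a clear message.
deposited_path <- function(file) {
  local <- system.file("extdata", file, package = "rhizoflux")
  if (nzchar(local) && file.exists(local)) return(local)
  repo <- file.path("..", "..", "inst", "extdata", file)
  if (file.exists(repo)) return(repo)
  stop("deposited data file '", file, "' is not available locally; ",
       "download it from the model repository into inst/extdata/ to run ",
       "the genome-scale reproduction checks", call. = FALSE)
}

load_deposited_model <- function() {
  read_cobra_json(deposited_path("iAQY970.json"))
}
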