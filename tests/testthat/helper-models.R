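# Locations of the curated R. etli genome-scale models (the published
# supplementary workbooks). They are not redistributed with this package;
# a user who has them can point the suite at local copies.
curated_model_path <- function(which = c("growing", "community")) {
  which <- match.arg(which)
  opt <- getOption(paste0("xfba.", which, "_model"), "")
  if (nzchar(opt) && file.exists(opt)) return(opt)
  p <- system.file("extdata", paste0("retli_", which, "_model.xlsx"),
                   package = "xfba")
  if (nzchar(p) && file.exists(p)) return(p)
  NA_character_
}

missing_model_msg <- function(which) {
  paste0("the curated R. etli ", which, " model (supplementary workbook) ",
         "is not distributed with this package and no local copy was ",
         "supplied via options(xfba.", which, "_model=); the published ",
         "rates cannot be recomputed without it")
}
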