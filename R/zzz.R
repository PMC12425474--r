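.onLoad <- function(libname, pkgname) {
  # built-in demographics plugin: the --participants pipeline step
  registerPlugin(
    name = "participants",
    option = "--participants",
    run = function(stepDir, corpus, context) {
      writeCsv(corpusDemographics(corpus),
               file.path(stepDir, "demographics.csv"))
    }
  )
}
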