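Package: phistruct
Title: Cause-Effect Structure Analysis of Discrete Causal Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyses the intrinsic causal powers of finite discrete causal
    networks described by transition probability matrices. Provides background
    conditioning of candidate systems, intrinsic cause and effect information,
    system integrated information over directional minimum partitions,
    recursive identification of maximal substrates (complexes), and the
    unfolding of a complex into its cause-effect structure of causal
    distinctions and relations, summarised by structure integrated
    information. Includes a builder for networks of weighted logistic units,
    generators for the standard example network families, JSON/YAML/TSV
    import and export, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
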