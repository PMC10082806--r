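# File formats

All coordinates in files are 0-based half-open. Tables are tab-separated;
columns are located by header name, never by position.

## Per-read methylation calls (input/output)

Header columns: `chromosome`, `strand`, `start`, `end`, `read_name`,
`log_lik_ratio`, `log_lik_methylated`, `log_lik_unmethylated`,
`num_calling_strands`, `num_motifs`, `sequence`. One row per read per CpG
group; `log_lik_ratio` is the methylated-vs-unmethylated log-likelihood
ratio. Mandatory for reading: `chromosome`, `strand`, `start`, `end`,
`read_name`, `log_lik_ratio`, `num_motifs`.

## Methylation frequency table (input/output)

Header columns: `chromosome`, `start`, `end`, `num_motifs_in_group`,
`called_sites`, `called_sites_methylated`, `methylated_frequency`,
`group_sequence`. One row per CpG group; beta is always recomputed as
`called_sites_methylated / called_sites` on read.

## Delta-beta track export (BED3+)

`#chrom`, `start`, `end`, `delta_beta`, `beta_test`, `beta_control`,
`called_sites_test`, `called_sites_control`.

## Segment export (BED6+)

`#chrom`, `start`, `end`, `segment_id`, `mean_delta_beta`, `strand` (`.`),
`n_cpgs`, `assigned_level`.

## DMR export (BED6+)

`#chrom`, `start`, `end`, `dmr_id`, `mean_delta_beta`, `strand` (`.`),
`n_cpg_groups`, `p_value`, `direction` (`hyper`/`hypo`), `cpg_density`
(CpG per 100 bp), `resolution_class` (`<=2`, `<=3`, `>3`); sorted by
coordinate. The annotated variant appends `cgi_context` (`CGI`/`NoCGI`),
`elements` (comma-separated `category:gene`), `region_group`
(`Reg`/`GB`/`3UTR`/`enhancer`/`intergenic`, possibly several) and `genes`.

## Features

* Feature BED: BED3/4/6; column 4 is the feature name (or category).
* Gene model TSV: `gene`, `transcript`, `chrom`, `strand`, `tss`,
  `exon_blocks` (`start-end,start-end,...`), optional `cds_start`,
  `cds_end`.
* Enhancer targets TSV: `chrom`, `start`, `end`, `gene` (precomputed
  mapping; no prediction).
* Chromosome sizes: two columns (name, length), no header.

## Run summary JSON

`n_total`, `n_hyper`, `n_hypo`, `kb_hyper`, `kb_hypo`, `frac_le2`,
`frac_le3` — counts and total genomic extent (kb) of the called DMRs and
the fraction at or below the 2 and 3 CpG/100 bp resolution limits.

## Benchmark score TSV

One row per replicate: `seed`, `cpg_precision`, `cpg_recall`, `cpg_f1`,
`dmr_tp`, `dmr_fp`, `dmr_fn`, `n_called`.
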