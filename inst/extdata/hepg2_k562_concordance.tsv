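gene	exon	deu_cell	dhm_mark	dhm_cell	eclip_rbp	eclip_cell
CD46	chr1:207790253-207790345	K562	H3K36me3	K562	TIA1	K562
MAP3K8	chr10:30437176-30437406	HepG2	H3K36me3	K562	TIA1	K562
TMTC4	chr13:100656381-100656468	K562	H3K36me3	HepG2	U2AF2	HepG2
ARF4	chr3:57577316-57577387	HepG2	H3K36me3	HepG2	U2AF2	K562
CD46	chr1:207790253-207790345	K562	H3K36me3	K562	U2AF2	HepG2
PUS7	chr7:105468337-105468463	K562	H3K36me3	K562	U2AF2	HepG2
RPS6KB1	chr17:59912684-59912804	K562	H3K36me3	K562	U2AF2	HepG2
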