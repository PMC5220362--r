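go_term	label
GO:0016032	viral process
GO:0019012	virion
GO:0019058	viral life cycle
GO:0019076	viral release from host cell
GO:0039693	viral DNA genome replication
GO:0046797	viral procapsid maturation
GO:0075713	establishment of integrated proviral latency
GO:0098689	latency-replication decision
GO:0019048	modulation by virus of host process
GO:0044826	viral genome integration into host DNA
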