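mirna	lfc	regulator
sim-miR-0003	-2	FALSE
sim-miR-0005	2	FALSE
sim-miR-0018	2	FALSE
sim-miR-0019	2	FALSE
sim-miR-0020	2	FALSE
sim-miR-0021	-2	FALSE
sim-miR-0024	2	FALSE
sim-miR-0026	-2	TRUE
sim-miR-0030	-2	TRUE
sim-miR-0031	-2	FALSE
sim-miR-0033	-2	TRUE
sim-miR-0036	2	FALSE
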