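mirna	gene
sim-miR-0001	gene00064
sim-miR-0001	gene00006
sim-miR-0001	gene00051
sim-miR-0001	gene00028
sim-miR-0001	gene00073
sim-miR-0001	gene00036
sim-miR-0002	gene00032
sim-miR-0002	gene00023
sim-miR-0002	gene00027
sim-miR-0002	gene00034
sim-miR-0002	gene00054
sim-miR-0002	gene00061
sim-miR-0003	gene00023
sim-miR-0003	gene00009
sim-miR-0003	gene00071
sim-miR-0003	gene00076
sim-miR-0003	gene00034
sim-miR-0003	gene00046
sim-miR-0004	gene00011
sim-miR-0004	gene00015
sim-miR-0004	gene00036
sim-miR-0004	gene00041
sim-miR-0004	gene00069
sim-miR-0004	gene00047
sim-miR-0005	gene00045
sim-miR-0005	gene00012
sim-miR-0005	gene00054
sim-miR-0005	gene00033
sim-miR-0005	gene00035
sim-miR-0005	gene00056
sim-miR-0006	gene00014
sim-miR-0006	gene00075
sim-miR-0006	gene00049
sim-miR-0006	gene00073
sim-miR-0006	gene00005
sim-miR-0006	gene00038
sim-miR-0007	gene00051
sim-miR-0007	gene00009
sim-miR-0007	gene00034
sim-miR-0007	gene00032
sim-miR-0007	gene00003
sim-miR-0007	gene00040
sim-miR-0008	gene00009
sim-miR-0008	gene00005
sim-miR-0008	gene00039
sim-miR-0008	gene00008
sim-miR-0008	gene00048
sim-miR-0008	gene00077
sim-miR-0009	gene00014
sim-miR-0009	gene00035
sim-miR-0009	gene00028
sim-miR-0009	gene00019
sim-miR-0009	gene00002
sim-miR-0009	gene00026
sim-miR-0010	gene00051
sim-miR-0010	gene00061
sim-miR-0010	gene00059
sim-miR-0010	gene00064
sim-miR-0010	gene00041
sim-miR-0010	gene00053
sim-miR-0011	gene00011
sim-miR-0011	gene00030
sim-miR-0011	gene00066
sim-miR-0011	gene00003
sim-miR-0011	gene00053
sim-miR-0011	gene00001
sim-miR-0012	gene00073
sim-miR-0012	gene00061
sim-miR-0012	gene00075
sim-miR-0012	gene00014
sim-miR-0012	gene00056
sim-miR-0012	gene00043
sim-miR-0013	gene00051
sim-miR-0013	gene00052
sim-miR-0013	gene00068
sim-miR-0013	gene00019
sim-miR-0013	gene00045
sim-miR-0013	gene00035
sim-miR-0014	gene00012
sim-miR-0014	gene00044
sim-miR-0014	gene00018
sim-miR-0014	gene00039
sim-miR-0014	gene00038
sim-miR-0014	gene00006
sim-miR-0015	gene00056
sim-miR-0015	gene00002
sim-miR-0015	gene00007
sim-miR-0015	gene00039
sim-miR-0015	gene00066
sim-miR-0015	gene00060
sim-miR-0016	gene00069
sim-miR-0016	gene00039
sim-miR-0016	gene00011
sim-miR-0016	gene00005
sim-miR-0016	gene00051
sim-miR-0016	gene00026
sim-miR-0017	gene00074
sim-miR-0017	gene00005
sim-miR-0017	gene00025
sim-miR-0017	gene00062
sim-miR-0017	gene00037
sim-miR-0017	gene00045
sim-miR-0018	gene00076
sim-miR-0018	gene00007
sim-miR-0018	gene00018
sim-miR-0018	gene00053
sim-miR-0018	gene00059
sim-miR-0018	gene00050
sim-miR-0019	gene00074
sim-miR-0019	gene00053
sim-miR-0019	gene00018
sim-miR-0019	gene00001
sim-miR-0019	gene00022
sim-miR-0019	gene00052
sim-miR-0020	gene00072
sim-miR-0020	gene00053
sim-miR-0020	gene00033
sim-miR-0020	gene00036
sim-miR-0020	gene00077
sim-miR-0020	gene00056
sim-miR-0021	gene00077
sim-miR-0021	gene00036
sim-miR-0021	gene00005
sim-miR-0021	gene00044
sim-miR-0021	gene00020
sim-miR-0021	gene00069
sim-miR-0022	gene00007
sim-miR-0022	gene00070
sim-miR-0022	gene00051
sim-miR-0022	gene00008
sim-miR-0022	gene00015
sim-miR-0022	gene00047
sim-miR-0023	gene00018
sim-miR-0023	gene00025
sim-miR-0023	gene00008
sim-miR-0023	gene00022
sim-miR-0023	gene00056
sim-miR-0023	gene00028
sim-miR-0024	gene00012
sim-miR-0024	gene00050
sim-miR-0024	gene00061
sim-miR-0024	gene00027
sim-miR-0024	gene00031
sim-miR-0024	gene00072
sim-miR-0025	gene00071
sim-miR-0025	gene00011
sim-miR-0025	gene00028
sim-miR-0025	gene00051
sim-miR-0025	gene00066
sim-miR-0025	gene00063
sim-miR-0026	gene00008
sim-miR-0026	gene00032
sim-miR-0026	gene00028
sim-miR-0026	gene00049
sim-miR-0026	gene00066
sim-miR-0026	gene00068
sim-miR-0027	gene00004
sim-miR-0027	gene00045
sim-miR-0027	gene00011
sim-miR-0027	gene00066
sim-miR-0027	gene00030
sim-miR-0027	gene00023
sim-miR-0028	gene00001
sim-miR-0028	gene00012
sim-miR-0028	gene00023
sim-miR-0028	gene00005
sim-miR-0028	gene00079
sim-miR-0028	gene00059
sim-miR-0029	gene00058
sim-miR-0029	gene00044
sim-miR-0029	gene00030
sim-miR-0029	gene00015
sim-miR-0029	gene00014
sim-miR-0029	gene00048
sim-miR-0030	gene00057
sim-miR-0030	gene00005
sim-miR-0030	gene00033
sim-miR-0030	gene00053
sim-miR-0030	gene00029
sim-miR-0030	gene00024
sim-miR-0031	gene00015
sim-miR-0031	gene00001
sim-miR-0031	gene00008
sim-miR-0031	gene00059
sim-miR-0031	gene00016
sim-miR-0031	gene00004
sim-miR-0032	gene00069
sim-miR-0032	gene00028
sim-miR-0032	gene00076
sim-miR-0032	gene00003
sim-miR-0032	gene00013
sim-miR-0032	gene00067
sim-miR-0033	gene00020
sim-miR-0033	gene00050
sim-miR-0033	gene00035
sim-miR-0033	gene00022
sim-miR-0033	gene00076
sim-miR-0033	gene00038
sim-miR-0034	gene00007
sim-miR-0034	gene00004
sim-miR-0034	gene00063
sim-miR-0034	gene00011
sim-miR-0034	gene00031
sim-miR-0034	gene00033
sim-miR-0035	gene00014
sim-miR-0035	gene00032
sim-miR-0035	gene00018
sim-miR-0035	gene00025
sim-miR-0035	gene00028
sim-miR-0035	gene00052
sim-miR-0036	gene00048
sim-miR-0036	gene00010
sim-miR-0036	gene00030
sim-miR-0036	gene00035
sim-miR-0036	gene00013
sim-miR-0036	gene00007
sim-miR-0037	gene00042
sim-miR-0037	gene00052
sim-miR-0037	gene00019
sim-miR-0037	gene00075
sim-miR-0037	gene00044
sim-miR-0037	gene00010
sim-miR-0038	gene00014
sim-miR-0038	gene00036
sim-miR-0038	gene00042
sim-miR-0038	gene00063
sim-miR-0038	gene00016
sim-miR-0038	gene00034
sim-miR-0039	gene00071
sim-miR-0039	gene00075
sim-miR-0039	gene00009
sim-miR-0039	gene00061
sim-miR-0039	gene00021
sim-miR-0039	gene00016
sim-miR-0040	gene00031
sim-miR-0040	gene00061
sim-miR-0040	gene00066
sim-miR-0040	gene00017
sim-miR-0040	gene00001
sim-miR-0040	gene00063
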