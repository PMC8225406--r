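# 128-channel scalp layout, 10-05 label set, unit-sphere head frame
# columns: label x y z
TP8h	0.873958	-0.469880	0.124139
CP6	0.831488	-0.460056	0.311412
C6	0.934162	-0.143011	0.326939
T8	0.978884	-0.172815	-0.109187
T8h	0.980498	-0.160155	0.113900
T7h	-0.977412	-0.175373	0.117943
T7	-0.976571	-0.185874	-0.108447
TP7	-0.876639	-0.475591	-0.072917
Cz	0.003983	-0.091066	0.995837
Oz	0.000929	-0.991960	0.126546
Fz	0.003526	0.660786	0.750566
Pz	0.002804	-0.700597	0.713552
Fpz	0.001272	0.999811	-0.019408
O1	-0.252329	-0.964666	0.075827
O2	0.256398	-0.963610	0.075607
F3	-0.595220	0.629189	0.499834
F4	0.606623	0.635512	0.477633
C3	-0.706876	-0.125802	0.696060
C4	0.720988	-0.117092	0.682983
P3	-0.480960	-0.714878	0.507570
P4	0.498504	-0.703519	0.506513
F7	-0.847627	0.512395	-0.137767
F8	0.846108	0.514567	-0.139004
P7	-0.701950	-0.711819	-0.024101
P8	0.706832	-0.706954	-0.024575
FC5	-0.929019	0.224309	0.294293
FC6	0.929583	0.233006	0.285628
CP5	-0.818335	-0.478616	0.318205
TP8	0.880320	-0.468673	-0.073370
AFp9	-0.388499	0.778403	-0.493110
AFp10	0.402826	0.770865	-0.493456
FC1	-0.375357	0.286639	0.881445
FC2	0.386023	0.293400	0.874587
A2	0.763880	-0.222674	-0.605725
A1	-0.765138	-0.222136	-0.604334
AF5	-0.527815	0.846515	0.069453
AF6	0.532467	0.843636	0.068970
CP2	0.351645	-0.431251	0.830884
AF2h	0.117940	0.909843	0.397838
CP1	-0.326425	-0.434692	0.839339
FFT9	-0.803541	0.294559	-0.517259
FFT10	0.806612	0.292101	-0.513861
FC3	-0.708119	0.267286	0.653548
FC4	0.717488	0.273238	0.640743
PO10	0.466253	-0.831739	-0.301361
FCz	0.004053	0.295142	0.955445
PO9	-0.465984	-0.832033	-0.300965
AFF1	-0.269068	0.797758	0.539616
TPP10	0.734870	-0.551562	-0.394647
TPP9	-0.733978	-0.551478	-0.396419
FT7	-0.976104	0.170633	-0.134558
FT8	0.973730	0.183483	-0.134845
F5	-0.784679	0.584687	0.205963
C1	-0.371708	-0.102635	0.922659
PO2	0.174950	-0.895916	0.408321
C2	0.390044	-0.099645	0.915389
PO1	-0.167158	-0.896633	0.410008
F6	0.791456	0.580704	0.190737
F2	0.335604	0.654987	0.677025
CPz	0.003504	-0.429705	0.902963
CP3	-0.618606	-0.457546	0.638732
I2h	0.124068	-0.968947	-0.213888
AFF9	-0.637108	0.565607	-0.523624
CP4	0.637648	-0.446439	0.627771
AFF10	0.645679	0.556880	-0.522478
PPO5	-0.537079	-0.811440	0.230457
PPO6	0.550805	-0.801617	0.232431
FCC5h	-0.853964	0.049200	0.518001
AFp4	0.273674	0.958112	0.084403
FCC4h	0.574513	0.086343	0.813928
FCC6h	0.860135	0.059601	0.506573
FCC3h	-0.564119	0.079309	0.821876
FTT9h	-0.942426	-0.020688	-0.333773
FFC3h	-0.514883	0.472593	0.715228
AFp3	-0.257768	0.963667	0.070013
FCC2h	0.200019	0.098460	0.974832
FTT10h	0.942981	-0.020270	-0.332229
P2	0.275926	-0.695760	0.663161
FFC5h	-0.785977	0.438882	0.435458
FCC1h	-0.192299	0.095987	0.976631
FFC2h	0.193085	0.483520	0.853772
FFC1h	-0.170550	0.482775	0.858977
AF10h	0.604391	0.728140	-0.323301
FFC6h	0.792168	0.446070	0.416523
FFC4h	0.529008	0.480202	0.699684
P1	-0.251075	-0.706414	0.661771
CCP5h	-0.799023	-0.310907	0.514684
AF9h	-0.601859	0.729008	-0.326057
CCP6h	0.808667	-0.296690	0.507969
I1	-0.244536	-0.939572	-0.239596
CCP2h	0.194217	-0.270369	0.942964
CCP3h	-0.527029	-0.287828	0.799622
CCP4h	0.542543	-0.279435	0.792189
TTP10h	0.900784	-0.328016	-0.284592
AFF4h	0.409880	0.783333	0.467320
FFT7h	-0.920283	0.386647	0.059862
TTP9h	-0.898126	-0.332675	-0.287572
CCP1h	-0.176726	-0.272702	0.945728
AF3h	-0.309361	0.894588	0.322503
FFT8h	0.919853	0.388688	0.052832
AFF5h	-0.598059	0.753948	0.271824
AFF7h	-0.721920	0.691896	0.010555
AFF6h	0.604936	0.751255	0.263946
PO8	0.495193	-0.868443	0.024285
C5	-0.927952	-0.159047	0.337058
AFF8h	0.723398	0.690394	0.007244
AF4	0.404395	0.880143	0.248623
F9h	-0.811953	0.466899	-0.350339
AFp2h	0.079923	0.979436	0.185249
AF1h	-0.104036	0.911732	0.397393
PO7	-0.489979	-0.871377	0.024946
AFFz	0.003130	0.807372	0.590034
CPP2h	0.168909	-0.570531	0.803719
F10h	0.813336	0.467254	-0.346638
F1	-0.314606	0.651404	0.690432
CPP6h	0.671302	-0.591312	0.446881
CPP4h	0.452850	-0.576249	0.680341
CPP3h	-0.427282	-0.589187	0.685776
CPP5h	-0.654281	-0.604904	0.453880
CPP1h	-0.139481	-0.578371	0.803761
PPO2h	0.120863	-0.804685	0.581269
FC4h	0.561937	0.286228	0.776081
FC3h	-0.551597	0.278905	0.786100
FC5h	-0.838518	0.245165	0.486602
TP7h	-0.865700	-0.484618	0.125337
FFC5	-0.873271	0.414328	0.256379
FC6h	0.842614	0.253256	0.475251
FT7h	-0.976287	0.199736	0.083476
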