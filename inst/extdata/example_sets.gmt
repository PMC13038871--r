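KRAS_SIG	synthetic example set	G00005	G00010	G00015	G00020	G00025	G00030	G00035	G00040	G00045	G00050	G00055	G00060	G00065	G00070	G00075	G00080	G00085	G00090	G00095	G00100	G00105	G00110	G00115	G00120	G00125	G00130	G00135	G00140	G00145	G00150	G00155	G00160	G00165	G00170	G00175	G00180	G00185	G00190	G00195	G00200
DUB_ACTIVITY	synthetic example set	G00003	G00010	G00017	G00024	G00031	G00038	G00045	G00052	G00059	G00066	G00073	G00080	G00087	G00094	G00101	G00108	G00115	G00122	G00129	G00136	G00143	G00150	G00157	G00164	G00171	G00178	G00185	G00192	G00199	G00206	G00213	G00220	G00227	G00234	G00241	G00248	G00255	G00262	G00269	G00276	G00283	G00290	G00297
EMT	synthetic example set	G00400	G00404	G00408	G00412	G00416	G00420	G00424	G00428	G00432	G00436	G00440	G00444	G00448	G00452	G00456	G00460	G00464	G00468	G00472	G00476	G00480	G00484	G00488	G00492	G00496	G00500	G00504	G00508	G00512	G00516	G00520	G00524	G00528	G00532	G00536	G00540	G00544	G00548	G00552	G00556	G00560	G00564	G00568	G00572	G00576	G00580	G00584	G00588	G00592	G00596	G00600	G00604	G00608	G00612	G00616	G00620	G00624	G00628	G00632	G00636	G00640	G00644	G00648	G00652	G00656	G00660	G00664	G00668	G00672	G00676	G00680	G00684	G00688	G00692	G00696	G00700
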