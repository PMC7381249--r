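sample_id,diagnosis,smoker,condition,pooled_n,mtx_mg_w,cdmard,biologics
1,RA,no,control,3,10;25;0,MTX;MTX;SLZ,TNFi;TNFi;TNFi
2,RA,yes,control,2,15;10,MTX;MTX,CTLA4;TNFi
3,HC,yes,control,2,0;0,No;No,No;No
4,HC,no,control,2,0;0,No;No,No;No
5,RA,yes,control,1,25,MTX,CTLA4
6,HC,no,control,1,0,No,No
7,RA,no,control,1,20,MTX,aCD20
8,HC,yes,control,1,0,No,No
9,RA,yes,control,1,25,MTX,TNFi
10,HC,no,control,1,0,No,No
11,RA,yes,control,2,25;0,SLZ+PQ;No,No;TNFi
12,HC,yes,control,1,0,No,No
13,RA,no,control,2,15;12.5,MTX;MTX,TNFi;TNFi
14,RA,yes,control,1,0,SLZ,TNFi
15,RA,yes,control,1,20,MTX,TNFi
16,RA,no,control,1,20,MTX,No
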